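# Independent oracles and small builders shared across tests.

# Brute-force total observation probability: explicit sum over all 2^T
# state paths. Independent of the forward recursion it checks.
enum_forward <- function(x, A, B, pi0) {
  T_ <- length(x)
  grid <- as.matrix(expand.grid(rep(list(1:2), T_)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    p <- pi0[s[1]] * B[s[1], x[1] + 1]
    if (T_ > 1) {
      for (t in 2:T_) p <- p * A[s[t - 1], s[t]] * B[s[t], x[t] + 1]
    }
    tot <- tot + p
  }
  tot
}

# Brute-force maximum path probability (and the argmax paths).
enum_viterbi <- function(x, A, B, pi0) {
  T_ <- length(x)
  grid <- as.matrix(expand.grid(rep(list(1:2), T_)))
  probs <- apply(grid, 1, function(s) {
    p <- pi0[s[1]] * B[s[1], x[1] + 1]
    if (T_ > 1) {
      for (t in 2:T_) p <- p * A[s[t - 1], s[t]] * B[s[t], x[t] + 1]
    }
    p
  })
  best <- max(probs)
  list(max_prob = best,
       argmax = grid[probs > best * (1 - 1e-12), , drop = FALSE])
}

random_hmm <- function() {
  nr <- function() {
    m <- matrix(stats::runif(4, 0.05, 1), 2, 2)
    m / rowSums(m)
  }
  suppressMessages(spikeburst::hmm_spec(nr(), nr(), stats::runif(2, 0.1, 1)))
}

# binned_rates object built directly from a matrix, for unit tests that
# need controlled rate values
make_rates <- function(m, step = 0.1, bin_width = 0.2, t_start = 0,
                       zscored = FALSE) {
  structure(
    list(matrix = m, bin_width = bin_width, step = step,
         bin_left_edges = t_start + (seq_len(ncol(m)) - 1) * step,
         t_start = t_start,
         t_stop = t_start + (ncol(m) - 1) * step + bin_width,
         zscored = zscored),
    class = "binned_rates"
  )
}

# homogeneous-Poisson population with no shared structure (null recordings)
poisson_population <- function(n_units, duration, rate, seed) {
  withr::with_seed(seed, {
    sp <- lapply(seq_len(n_units), function(u) {
      sort(stats::runif(stats::rpois(1, rate * duration), 0, duration))
    })
    names(sp) <- sprintf("p%03d", seq_len(n_units))
    spikeburst::spike_train_set(sp, 0, duration)
  })
}
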