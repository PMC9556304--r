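# Two-state discrete-emission hidden Markov segmentation of population
# activity into bursts ("on") and inter-burst intervals ("off"). The binary
# observable is the thresholded population-mean z-scored rate; parameters
# are re-estimated by Baum-Welch with scaled forward-backward recursions
# (numerically safe for >= 1e5 bins) and the state sequence is decoded with
# log-space Viterbi. This module is fully deterministic.

#' Binarize population activity
#'
#' Symbol i is 1 iff the mean over units of the z-scored rate in bin i is
#' strictly above `threshold` (default 0, i.e. above-average population
#' activity), else 0.
#'
#' @param rates A z-scored `binned_rates` object (see [zscore_rates()]).
#' @param threshold Binarization threshold in z-units (default 0).
#' @return An object of class `obs_sequence` carrying the symbols and the
#'   source bin geometry.
#' @export
binarize_population <- function(rates, threshold = 0) {
  stopifnot(inherits(rates, "binned_rates"))
  if (!isTRUE(rates$zscored)) {
    stop("binarize_population requires z-scored rates; call zscore_rates() first")
  }
  symbols <- as.integer(population_trace(rates) > threshold)
  structure(
    list(symbols = symbols, threshold = threshold,
         bin_width = rates$bin_width, step = rates$step,
         bin_left_edges = rates$bin_left_edges,
         t_start = rates$t_start, t_stop = rates$t_stop),
    class = "obs_sequence"
  )
}

#' Construct a two-state HMM specification
#'
#' Rows of the transition and emission matrices must be normalizable; rows
#' that do not already sum to 1 are row-normalized with a message (printed
#' literature initial guesses are not always exactly stochastic).
#'
#' @param transition 2x2 matrix, `transition[i, j] = P(state j | state i)`.
#' @param emission 2x2 matrix, `emission[i, k] = P(symbol k-1 | state i)`.
#' @param initial Length-2 initial state distribution (default uniform).
#' @param loglik_trace Optional per-iteration log-likelihood trace.
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(transition, emission, initial = c(0.5, 0.5),
                     loglik_trace = numeric(0)) {
  transition <- as.matrix(transition); emission <- as.matrix(emission)
  stopifnot(all(dim(transition) == c(2, 2)), all(dim(emission) == c(2, 2)),
            length(initial) == 2)
  if (any(transition < 0) || any(emission < 0) || any(initial < 0)) {
    stop("HMM parameters must be non-negative")
  }
  norm_rows <- function(m, what) {
    s <- rowSums(m)
    if (any(s <= 0)) stop(what, " has a zero row")
    if (any(abs(s - 1) > 1e-12)) {
      message(what, " rows re-normalized (row sums were ",
              paste(format(s, digits = 6), collapse = ", "), ")")
    }
    m / s
  }
  structure(
    list(transition = norm_rows(transition, "transition"),
         emission = norm_rows(emission, "emission"),
         initial = initial / sum(initial),
         loglik_trace = loglik_trace),
    class = "hmm_spec"
  )
}

#' Default initial HMM guesses
#'
#' The conventional starting point for burst segmentation: transition
#' `[0.95, 0.05; 0.05, 0.96]` and emission `[0.5, 0.5; 0.1, 0.99]`,
#' row-normalized (state 2 is the burst-like state, emitting symbol 1 with
#' high probability).
#'
#' @return An `hmm_spec`.
#' @export
hmm_init_default <- function() {
  suppressMessages(hmm_spec(
    transition = matrix(c(0.95, 0.05, 0.05, 0.96), 2, 2, byrow = TRUE),
    emission = matrix(c(0.5, 0.5, 0.1, 0.99), 2, 2, byrow = TRUE)
  ))
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("<hmm_spec> transition:\n"); print(round(x$transition, 4))
  cat("emission:\n"); print(round(x$emission, 4))
  if (length(x$loglik_trace)) {
    cat("fitted: ", length(x$loglik_trace), " iterations, logLik ",
        format(utils::tail(x$loglik_trace, 1)), "\n", sep = "")
  }
  invisible(x)
}

check_obs <- function(obs) {
  symbols <- if (inherits(obs, "obs_sequence")) obs$symbols else as.integer(obs)
  if (length(symbols) < 1) stop("empty observation sequence")
  if (!all(symbols %in% c(0L, 1L))) {
    stop("observation symbols must be 0 or 1")
  }
  symbols
}

# scaled forward-backward; returns alpha, beta (scaled), scale factors c,
# and the log-likelihood sum(log(c))
forward_backward <- function(x, A, B, pi0) {
  T_ <- length(x)
  o <- x + 1L
  alpha <- matrix(0, T_, 2); cc <- numeric(T_)
  a <- pi0 * B[, o[1]]
  cc[1] <- sum(a)
  if (cc[1] <= 0) {
    stop("zero-probability observation at t=1; a symbol has probability 0 ",
         "under both states -- smooth the emission initial guess")
  }
  alpha[1, ] <- a / cc[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- (alpha[t - 1, ] %*% A)[1, ] * B[, o[t]]
      cc[t] <- sum(a)
      if (cc[t] <= 0) {
        stop("zero-probability observation at t=", t,
             "; smooth the emission initial guess")
      }
      alpha[t, ] <- a / cc[t]
    }
  }
  beta <- matrix(0, T_, 2)
  beta[T_, ] <- 1
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      beta[t, ] <- (A %*% (B[, o[t + 1]] * beta[t + 1, ]))[, 1] / cc[t + 1]
    }
  }
  list(alpha = alpha, beta = beta, scale = cc, loglik = sum(log(cc)))
}

#' Fit a two-state binary-emission HMM by Baum-Welch
#'
#' Expectation-maximization with scaled forward-backward recursions.
#' Iteration stops when the relative log-likelihood improvement drops below
#' `tol` or after `max_iter` iterations; the per-iteration log-likelihood
#' trace is retained (it is non-decreasing up to numerical slack).
#'
#' @param obs An [binarize_population()] result or a 0/1 vector (length >= 2).
#' @param init Initial `hmm_spec` (default [hmm_init_default()]).
#' @param tol Relative log-likelihood convergence threshold (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A fitted `hmm_spec` with `loglik_trace`, `n_iter`, `converged`.
#' @export
baum_welch <- function(obs, init = hmm_init_default(), tol = 1e-6,
                       max_iter = 500) {
  x <- check_obs(obs)
  if (length(x) < 2) stop("need at least 2 observations to fit transitions")
  stopifnot(inherits(init, "hmm_spec"))
  A <- init$transition; B <- init$emission; pi0 <- init$initial
  o <- x + 1L
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(x, A, B, pi0)
    trace <- c(trace, fb$loglik)
    T_ <- length(x)
    gamma <- fb$alpha * fb$beta
    gamma <- gamma / rowSums(gamma)
    # xi sums: sum_t alpha_t(i) A(i,j) B(j, o_{t+1}) beta_{t+1}(j) / c_{t+1}
    W <- t(B)[o[2:T_], , drop = FALSE] * fb$beta[2:T_, , drop = FALSE] /
      fb$scale[2:T_]
    xi_sum <- (t(fb$alpha[1:(T_ - 1), , drop = FALSE]) %*% W) * A
    A_new <- xi_sum / rowSums(xi_sum)
    g1 <- colSums(gamma[x == 0L, , drop = FALSE])
    g_tot <- colSums(gamma)
    B_new <- cbind(g1 / g_tot, 1 - g1 / g_tot)
    pi_new <- gamma[1, ]
    if (iter > 1) {
      prev <- trace[iter - 1]
      rel <- (fb$loglik - prev) / max(abs(prev), .Machine$double.eps)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    A <- A_new; B <- B_new; pi0 <- pi_new
  }
  out <- suppressMessages(hmm_spec(A, B, pi0, loglik_trace = trace))
  out$n_iter <- length(trace)
  out$converged <- converged
  out
}

#' Decode the maximum-probability state path (Viterbi)
#'
#' Log-space dynamic program. The "on" (burst) state is the state whose
#' emission probability of symbol 1 is larger (tie: the second state); ties
#' in path score are broken toward the lower state index at each backtrack
#' step, so a fully symmetric model decodes to the all-off path.
#'
#' @param obs An `obs_sequence` or 0/1 vector.
#' @param model An `hmm_spec`.
#' @return An object of class `state_path`: per-bin labels `"off"`/`"on"`,
#'   the model-state indices, the on-state index, the log joint probability
#'   of the path, and the source bin geometry (when available).
#' @export
viterbi <- function(obs, model) {
  x <- check_obs(obs)
  stopifnot(inherits(model, "hmm_spec"))
  A <- log(model$transition); B <- log(model$emission)
  pi0 <- log(model$initial)
  o <- x + 1L
  T_ <- length(x)
  delta <- matrix(-Inf, T_, 2)
  psi <- matrix(1L, T_, 2)
  delta[1, ] <- pi0 + B[, o[1]]
  if (T_ > 1) {
    for (t in 2:T_) {
      for (j in 1:2) {
        cand <- delta[t - 1, ] + A[, j]
        psi[t, j] <- which.max(cand)       # first max = lower index on ties
        delta[t, j] <- cand[psi[t, j]] + B[j, o[t]]
      }
    }
  }
  states <- integer(T_)
  states[T_] <- which.max(delta[T_, ])
  if (T_ > 1) for (t in (T_ - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  on_state <- if (model$emission[2, 2] >= model$emission[1, 2]) 2L else 1L
  structure(
    list(states = ifelse(states == on_state, "on", "off"),
         state_index = states, on_state_index = on_state,
         log_prob = max(delta[T_, ]),
         bin_width = if (inherits(obs, "obs_sequence")) obs$bin_width else NA,
         step = if (inherits(obs, "obs_sequence")) obs$step else NA,
         bin_left_edges = if (inherits(obs, "obs_sequence")) {
           obs$bin_left_edges
         } else {
           NULL
         },
         t_start = if (inherits(obs, "obs_sequence")) obs$t_start else NA,
         t_stop = if (inherits(obs, "obs_sequence")) obs$t_stop else NA),
    class = "state_path"
  )
}

#' @export
print.state_path <- function(x, ...) {
  cat("<state_path> ", length(x$states), " bins, ",
      sum(x$states == "on"), " on (log prob ", format(x$log_prob), ")\n",
      sep = "")
  invisible(x)
}

#' Forward likelihood of an observation sequence
#'
#' Total probability of the observations under the model (all state paths
#' summed), computed with the scaled forward recursion.
#'
#' @param obs An `obs_sequence` or 0/1 vector.
#' @param model An `hmm_spec`.
#' @param log Return the log-likelihood (default) or the raw likelihood.
#' @return Numeric scalar.
#' @export
forward_likelihood <- function(obs, model, log = TRUE) {
  x <- check_obs(obs)
  ll <- forward_backward(x, model$transition, model$emission,
                         model$initial)$loglik
  if (log) ll else exp(ll)
}
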