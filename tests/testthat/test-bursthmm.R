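test_that("binarization thresholds the population-mean z trace", {
  z <- make_rates(rbind(a = c(-1, 0.5, 2, -0.2), b = c(-1, 0.5, 2, -0.2)),
                  zscored = TRUE)
  obs <- binarize_population(z)
  expect_equal(obs$symbols, c(0L, 1L, 1L, 0L))
  flipped <- z; flipped$matrix <- -flipped$matrix
  expect_equal(binarize_population(flipped)$symbols, 1L - obs$symbols)

  all_zero <- make_rates(matrix(0, 2, 5), zscored = TRUE)
  expect_equal(binarize_population(all_zero)$symbols, rep(0L, 5))
  expect_error(binarize_population(make_rates(matrix(1, 2, 5))), "z-scored")
})

test_that("default initial guesses are the printed matrices, row-normalized", {
  init <- hmm_init_default()
  expect_equal(init$transition[1, ], c(0.95, 0.05))
  expect_equal(init$transition[2, ], c(0.05, 0.96) / 1.01)
  expect_equal(init$emission[1, ], c(0.5, 0.5))
  expect_equal(init$emission[2, ], c(0.1, 0.99) / 1.09)
  expect_message(hmm_spec(matrix(c(1, 1, 1, 1), 2), diag(2) + 0.01),
                 "re-normalized")
})

test_that("forward likelihood equals brute-force path enumeration", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  B <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  model <- hmm_spec(A, B, c(0.5, 0.5))
  # enumeration over the 4 paths gives 0.19 for obs = (0, 1)
  expect_equal(enum_forward(c(0L, 1L), A, B, c(0.5, 0.5)), 0.19)
  expect_equal(forward_likelihood(c(0L, 1L), model, log = FALSE), 0.19)

  withr::with_seed(101, {
    for (i in 1:60) {
      m <- random_hmm()
      T_ <- sample(2:12, 1)
      x <- sample(0:1, T_, replace = TRUE)
      expect_equal(forward_likelihood(x, m, log = FALSE),
                   enum_forward(x, m$transition, m$emission, m$initial),
                   tolerance = 1e-10)
    }
  })
})

test_that("Viterbi equals the brute-force argmax over all paths", {
  withr::with_seed(202, {
    for (i in 1:200) {
      m <- random_hmm()
      T_ <- sample(2:8, 1)
      x <- sample(0:1, T_, replace = TRUE)
      vit <- viterbi(x, m)
      oracle <- enum_viterbi(x, m$transition, m$emission, m$initial)
      expect_equal(exp(vit$log_prob), oracle$max_prob, tolerance = 1e-10)
      if (nrow(oracle$argmax) == 1) {
        expect_equal(vit$state_index, unname(oracle$argmax[1, ]))
      }
    }
  })
})

test_that("identity emission decodes the observations themselves", {
  m <- suppressMessages(hmm_spec(matrix(0.5, 2, 2), diag(2)))
  x <- c(0L, 1L, 1L, 0L, 1L)
  expect_equal(viterbi(x, m)$state_index - 1L, x)
})

test_that("a fully symmetric model decodes to the all-off path", {
  m <- suppressMessages(hmm_spec(matrix(0.5, 2, 2), matrix(0.5, 2, 2)))
  vit <- viterbi(c(0L, 1L, 0L, 1L), m)
  expect_equal(vit$on_state_index, 2L)     # tie in P(symbol 1) -> state 2
  expect_true(all(vit$states == "off"))    # score ties -> lower state index
})

test_that("Baum-Welch log-likelihood is non-decreasing and rows stochastic", {
  withr::with_seed(303, {
    for (i in 1:10) {
      x <- sample(0:1, 400, replace = TRUE,
                  prob = c(runif(1, 0.2, 0.8), 1))
      fit <- baum_welch(x, init = random_hmm(), max_iter = 60)
      expect_true(all(diff(fit$loglik_trace) >= -1e-9))
      expect_equal(rowSums(fit$transition), c(1, 1), tolerance = 1e-12)
      expect_equal(rowSums(fit$emission), c(1, 1), tolerance = 1e-12)
      expect_true(all(fit$transition >= 0 & fit$transition <= 1))
    }
  })
})

test_that("degenerate all-ones sequence keeps a monotone trace", {
  fit <- baum_welch(rep(1L, 50))
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  # the on state absorbs all emission mass for symbol 1
  expect_gt(fit$emission[2, 2], 0.99)
})

test_that("symbols outside {0,1} and degenerate inits are rejected", {
  expect_error(baum_welch(c(0L, 2L)), "0 or 1")
  lock <- suppressMessages(
    hmm_spec(matrix(0.5, 2, 2), matrix(c(1, 1, 0, 0), 2, 2))
  )
  expect_error(baum_welch(c(0L, 1L, 0L), init = lock), "smooth")
})

test_that("long recordings fit without underflow", {
  withr::with_seed(404, x <- sample(0:1, 1e5, replace = TRUE))
  fit <- baum_welch(x, max_iter = 5)
  expect_true(is.finite(utils::tail(fit$loglik_trace, 1)))
})

test_that("run labelling merges flicker and applies the duration convention", {
  mk_path <- function(states, step = 0.1, bw = 0.2) {
    structure(list(states = states, state_index = (states == "on") + 1L,
                   on_state_index = 2L, log_prob = 0,
                   bin_width = bw, step = step,
                   bin_left_edges = (seq_along(states) - 1) * step,
                   t_start = 0,
                   t_stop = (length(states) - 1) * step + bw),
              class = "state_path")
  }
  b <- label_bursts(mk_path(c("off", "on", "on", "on", "off")))
  on_runs <- b[b$state == "on", ]
  expect_equal(nrow(on_runs), 1)
  expect_equal(on_runs$duration_s, 0.2)    # (3 - 1) * 0.1
  expect_true(on_runs$interior)

  lead <- label_bursts(mk_path(c("on", "on", "off", "off", "off", "off")))
  expect_false(lead$interior[lead$state == "on"])

  none <- label_bursts(mk_path(rep("off", 6)))
  expect_equal(sum(none$state == "on"), 0)

  # single-bin flicker is merged into the flanking state
  flick <- label_bursts(mk_path(c("off", "off", "on", "off", "off", "off")))
  expect_equal(nrow(flick), 1)
  expect_equal(flick$state, "off")
})

test_that("burst statistics follow the hand-computed example", {
  sts <- spike_train_set(list(A = c(1.1, 1.2), B = numeric(0)), 0, 3)
  tab <- structure(
    data.frame(start_s = c(0.5, 1.0, 1.5), end_s = c(1.0, 1.5, 3.0),
               duration_s = c(0.5, 0.5, 1.5),
               state = c("off", "on", "off"),
               interior = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE),
    class = c("burst_table", "data.frame"), step = 0.1, bin_width = 0.2)
  st <- burst_statistics(tab, sts)
  expect_equal(st$recruitment, 0.5)
  expect_equal(st$mean_spikes_per_burst, 2)
  expect_true(st$defined)

  tab0 <- tab; tab0$interior <- FALSE
  st0 <- burst_statistics(tab0, sts)
  expect_false(st0$defined)
  expect_true(is.na(st0$mean_duration_s))
})

test_that("recruitment is 1 when every unit spikes in every burst", {
  sim <- simulate_population(synth_config(duration = 120, n_units = 10,
                                          recruit_prob = 1, spikes_mean = 8,
                                          noise_rate = 0, seed = 15))
  pl <- burst_pipeline(sim$spikes)
  expect_equal(pl$stats$recruitment, 1)
})

test_that("fitted self-transitions recover a geometric-dwell generator", {
  # oracle: empirical self-transitions of the TRUE latent state sampled at
  # the bin centres (this is what a bin-resolution HMM can see)
  for (s in 1:3) {
    cfg <- synth_config(
      duration = 600, n_units = 32,
      on_dwell = dwell_spec("geometric", mean = 0.46),
      off_dwell = dwell_spec("geometric", mean = 2.0),
      seed = s
    )
    sim <- simulate_population(cfg)
    pl <- burst_pipeline(sim$spikes)
    centres <- pl$obs$bin_left_edges + pl$obs$bin_width / 2
    iv <- sim$ground_truth$state_intervals
    true_state <- iv$state[findInterval(centres, iv$start)]
    trans <- table(head(true_state, -1), tail(true_state, -1))
    p_on <- trans["on", "on"] / sum(trans["on", ])
    p_off <- trans["off", "off"] / sum(trans["off", ])
    on_i <- pl$path$on_state_index
    expect_lt(abs(pl$model$transition[on_i, on_i] - p_on), 0.05)
    expect_lt(abs(pl$model$transition[3 - on_i, 3 - on_i] - p_off), 0.05)
  }
})
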