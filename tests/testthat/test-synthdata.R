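test_that("degenerate single-burst config recruits every unit inside bounds", {
  cfg <- suppressWarnings(
    synth_config(duration = 10, n_units = 20,
                 on_dwell = dwell_spec("gamma", shape = 4, scale = 1e4),
                 off_dwell = dwell_spec("gamma", shape = 4, scale = 1e-4),
                 recruit_prob = 1, noise_rate = 0, spikes_mean = 2,
                 seed = 11)
  )
  sim <- simulate_population(cfg)
  counts <- lengths(sim$spikes$spikes)
  expect_true(all(counts >= 1))           # 1 + Poisson(2) per recruited burst
  all_sp <- unlist(sim$spikes$spikes)
  expect_true(all(all_sp >= 0 & all_sp <= 10))
  expect_equal(sum(sim$ground_truth$state_intervals$state == "on"), 1)
})

test_that("on-interval count matches the renewal-theory expectation", {
  # 600 s with mean cycle 0.46 + 2.0 s => ~243.9 cycles; averaging seeds
  # shrinks the per-seed s.d. (~6.5) well below the +/-5 band used here
  n_on <- vapply(1:25, function(s) {
    cfg <- synth_config(duration = 600, n_units = 1, noise_rate = 0, seed = s)
    sum(simulate_population(cfg)$ground_truth$state_intervals$state == "on")
  }, numeric(1))
  expect_lt(abs(mean(n_on) - 600 / 2.46), 5)
})

test_that("identical seeds give identical output; RNG state is not leaked", {
  cfg <- synth_config(duration = 60, n_units = 8, seed = 99)
  set.seed(123); before <- runif(1)
  a <- simulate_population(cfg)
  set.seed(123); runif(1)
  b <- simulate_population(cfg)
  after <- runif(1)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
  expect_identical(a$ground_truth, b$ground_truth)
  set.seed(123); runif(1); expect_identical(runif(1), after)
})

test_that("ground-truth intervals tile the recording with alternating states", {
  for (s in c(2, 17)) {
    gt <- simulate_population(synth_config(duration = 120, n_units = 2,
                                           seed = s))$ground_truth
    iv <- gt$state_intervals
    expect_equal(iv$start[1], 0)
    expect_equal(iv$end[nrow(iv)], 120)
    expect_equal(iv$start[-1], iv$end[-nrow(iv)])
    expect_true(all(iv$state[-1] != iv$state[-nrow(iv)]))
  }
})

test_that("spike trains are sorted and fall inside the recording", {
  sim <- simulate_population(synth_config(duration = 120, seed = 5))
  for (sp in sim$spikes$spikes) {
    expect_false(is.unsorted(sp))
    expect_true(all(sp >= 0 & sp <= 120))
  }
})

test_that("fraction of units firing in a true burst matches q + noise term", {
  q <- 0.6; noise <- 0.5
  cfg <- synth_config(duration = 400, n_units = 40, recruit_prob = q,
                      noise_rate = noise, seed = 21)
  sim <- simulate_population(cfg)
  iv <- sim$ground_truth$state_intervals
  bursts <- iv[iv$state == "on", ]
  frac <- vapply(seq_len(nrow(bursts)), function(b) {
    mean(vapply(sim$spikes$spikes, function(sp) {
      any(sp >= bursts$start[b] & sp <= bursts$end[b])
    }, logical(1)))
  }, numeric(1))
  expected <- q + (1 - q) * (1 - exp(-noise * (bursts$end - bursts$start)))
  expect_lt(abs(mean(frac) - mean(expected)), 0.03)
})

test_that("different seeds give distributionally indistinguishable bursts", {
  durs <- vapply(1:20, function(s) {
    iv <- simulate_population(synth_config(duration = 200, n_units = 1,
                                           seed = s))$ground_truth$state_intervals
    mean(iv$end[iv$state == "on"] - iv$start[iv$state == "on"])
  }, numeric(1))
  p <- suppressWarnings(stats::ks.test(durs[1:10], durs[11:20]))$p.value
  expect_gt(p, 0.01)
})

test_that("stimulus events respect count, separation and edge guards", {
  cfg <- synth_config(duration = 1200, n_units = 4, n_events = 50,
                      n_modulated = 0, evoked_kernel = evoked_kernel("alpha"),
                      seed = 8)
  sim <- simulate_stimulus_session(cfg)
  expect_equal(n_events(sim$events), 50L)
  expect_false(is.unsorted(sim$events$onsets))
  expect_true(all(diff(sim$events$onsets) >= 4))
  expect_true(all(sim$events$onsets >= 2 &
                    sim$events$onsets <= 1200 - 2))
  expect_error(simulate_stimulus_session(
    synth_config(duration = 30, n_events = 50, n_modulated = 0,
                 evoked_kernel = evoked_kernel("alpha"), seed = 1)
  ), "cannot place")
})

test_that("a zero-amplitude kernel leaves the recording unmodulated", {
  cfg <- synth_config(duration = 300, n_units = 6, n_events = 10,
                      n_modulated = 3,
                      evoked_kernel = evoked_kernel("alpha", amplitude = 0),
                      seed = 13)
  sim <- simulate_stimulus_session(cfg)
  expect_length(sim$ground_truth$modulated_units, 0)
  base <- simulate_population(synth_config(duration = 300, n_units = 6,
                                           seed = 13))
  expect_identical(sim$spikes$spikes, base$spikes$spikes)
})

test_that("alpha-kernel evoked mass in (0, 1 s] matches the closed form", {
  # integral of A*(t/tau)*exp(1 - t/tau) over (0, 1]:
  # A*e*tau*(1 - exp(-1/tau)*(1 + 1/tau)) ~= 4.826 for A = 6, tau = 0.65
  A <- 6; tau <- 0.65
  closed <- A * exp(1) * tau * (1 - exp(-1 / tau) * (1 + 1 / tau))
  cfg <- synth_config(duration = 6000, n_units = 1, n_modulated = 1,
                      n_events = 1000, noise_rate = 0, recruit_prob = 0,
                      evoked_kernel = evoked_kernel("alpha", amplitude = A,
                                                    peak_time = tau),
                      seed = 31)
  sim <- simulate_stimulus_session(cfg)
  sp <- sim$spikes$spikes[[1]]
  per_event <- vapply(sim$events$onsets, function(e) {
    sum(sp > e & sp <= e + 1)
  }, numeric(1))
  expect_lt(abs(mean(per_event) - closed) / closed, 0.05)
})

test_that("light protocol: pulse spacing and the deterministic limit", {
  cfg <- synth_config(duration = 30, n_units = 6, noise_rate = 0,
                      recruit_prob = 0,
                      optotag_spec = optotag_spec(n_tagged = 3,
                                                  reliability = 1,
                                                  jitter_ms = 0),
                      seed = 4)
  sim <- simulate_light_protocol(cfg)
  expect_equal(diff(sim$events$onsets), rep(0.5, 9))
  for (u in sim$ground_truth$tagged_units) {
    sp <- sim$spikes$spikes[[u]]
    hits <- vapply(sim$events$onsets, function(o) {
      sum(sp > o & sp <= o + 0.010)
    }, numeric(1))
    expect_equal(hits, rep(1, 10))
  }
  for (u in setdiff(sim$spikes$unit_ids, sim$ground_truth$tagged_units)) {
    expect_length(sim$spikes$spikes[[u]], 0)
  }
})

test_that("per-unit answered-pulse counts follow Binomial(10, reliability)", {
  cfg <- synth_config(duration = 30, n_units = 1000, noise_rate = 0,
                      recruit_prob = 0,
                      optotag_spec = optotag_spec(n_tagged = 1000,
                                                  reliability = 0.7),
                      seed = 6)
  sim <- simulate_light_protocol(cfg)
  counts <- vapply(sim$spikes$spikes, function(sp) {
    sum(vapply(sim$events$onsets, function(o) {
      any(sp > o & sp <= o + 0.010)
    }, logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 7), 3 * sqrt(10 * 0.7 * 0.3 / 1000))
  expect_lt(abs(var(counts) - 10 * 0.7 * 0.3) / (10 * 0.7 * 0.3), 0.2)
})

test_that("behaviour fixture evaluates the stated deterministic formulas", {
  cohort <- fixture_F1()
  a1_d15 <- cohort[[1]][[15]]
  expect_equal(a1_d15$total_blue_licks, 94)
  expect_equal(a1_d15$total_red_licks, 40)
  traj <- session_preferences(cohort)
  a9 <- traj[traj$animal == "A9", ]
  expect_equal(a9$preference, rep(0, 15))
})

test_that("non-learner cohorts have near-zero mean preference", {
  cohort <- simulate_behavior_cohort(50, 5, FALSE, seed = 77)
  traj <- session_preferences(cohort)
  expect_lt(abs(mean(traj$preference, na.rm = TRUE)), 0.05)
})

test_that("learners' blue licks rise across days while red stays flat", {
  cohort <- simulate_behavior_cohort(20, 10, TRUE, seed = 55)
  traj <- session_preferences(cohort)
  day_means_blue <- tapply(traj$blue_licks, traj$day, mean)
  day_means_red <- tapply(traj$red_licks, traj$day, mean)
  expect_gt(day_means_blue[10], day_means_blue[1] + 30)
  expect_lt(abs(day_means_red[10] - day_means_red[1]), 10)
})

test_that("invalid configurations are rejected with clear failures", {
  expect_error(synth_config(duration = 0), "duration")
  expect_error(synth_config(n_units = 0), "n_units")
  expect_error(synth_config(recruit_prob = 1.2), "recruit_prob")
  expect_error(optotag_spec(reliability = 1.5), "reliability")
  expect_warning(
    synth_config(on_dwell = dwell_spec("gamma", shape = 1, scale = 0.005)),
    "time resolution"
  )
})
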