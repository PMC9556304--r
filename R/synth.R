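# Synthetic recordings and behaviour logs with known ground truth. The
# generative model mirrors what the analysis assumes: a shared latent on/off
# bursting process (gamma dwell times by default), per-burst partial unit
# recruitment, uniform within-burst spiking, low homogeneous noise,
# stimulus-evoked alpha/boxcar rate kernels added by superposition, and
# short-latency high-reliability light-evoked spikes. All randomness flows
# from one seed per call (withr::with_seed); no global RNG state leaks.

#' Specify a dwell-time distribution
#'
#' @param family `"gamma"` (default for realism at 200-ms analysis
#'   resolution) or `"geometric"` (memoryless at a 10-ms tick, for
#'   Markov-consistency checks).
#' @param shape,scale Gamma parameters (mean `shape * scale` seconds).
#' @param mean Mean dwell (seconds) for the geometric family.
#' @param tick Tick size of the geometric family (seconds, default 0.01).
#' @return A dwell-spec list.
#' @export
dwell_spec <- function(family = c("gamma", "geometric"), shape = 4,
                       scale = NULL, mean = NULL, tick = 0.01) {
  family <- match.arg(family)
  if (family == "gamma") {
    if (is.null(scale)) stop("gamma dwell needs a scale")
    if (shape <= 0 || scale <= 0) stop("dwell parameters must be positive")
    list(family = "gamma", shape = shape, scale = scale,
         mean = shape * scale)
  } else {
    if (is.null(mean)) stop("geometric dwell needs a mean")
    if (mean <= 0 || tick <= 0) stop("dwell parameters must be positive")
    list(family = "geometric", mean = mean, tick = tick)
  }
}

draw_dwells <- function(spec, n) {
  if (spec$family == "gamma") {
    stats::rgamma(n, shape = spec$shape, scale = spec$scale)
  } else {
    # dwell = tick * (1 + Geom(p)); mean = tick / p
    p <- min(1, spec$tick / spec$mean)
    spec$tick * (1 + stats::rgeom(n, p))
  }
}

#' Build a synthetic-recording configuration
#'
#' Defaults emulate the recorded population statistics the pipeline is
#' designed to recover: ~460-ms bursts separated by ~2-s silent periods
#' (gamma dwell times, shape 4), 73% per-burst unit recruitment, 1+Poisson(2)
#' spikes per recruited (unit, burst) pair, and 0.05 Hz homogeneous noise.
#'
#' @param duration Recording length, seconds.
#' @param n_units Number of units.
#' @param on_dwell,off_dwell [dwell_spec()]s for burst / silent durations.
#' @param recruit_prob Probability a unit participates in a given burst.
#' @param spikes_mean Poisson mean mu of the per-recruited-burst spike count
#'   `1 + Poisson(mu)`.
#' @param noise_rate Homogeneous background rate per unit, Hz.
#' @param evoked_kernel Optional evoked-rate kernel, see [evoked_kernel()].
#' @param n_events Number of stimulus events for stimulus sessions.
#' @param n_modulated Number of units receiving the evoked kernel.
#' @param optotag_spec Optional list for light protocols, see
#'   [optotag_spec()].
#' @param seed Integer seed; every random draw of a simulation flows from it.
#' @param time_resolution Generator tick, seconds (used for dwell sanity
#'   warnings).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(duration = 600, n_units = 64,
                         on_dwell = dwell_spec("gamma", shape = 4, scale = 0.115),
                         off_dwell = dwell_spec("gamma", shape = 4, scale = 0.5),
                         recruit_prob = 0.73, spikes_mean = 2,
                         noise_rate = 0.05, evoked_kernel = NULL,
                         n_events = 50, n_modulated = 0,
                         optotag_spec = NULL, seed = 1,
                         time_resolution = 0.01) {
  if (duration <= 0) stop("duration must be positive")
  if (n_units < 1) stop("n_units must be at least 1")
  if (recruit_prob < 0 || recruit_prob > 1) stop("recruit_prob must be in [0, 1]")
  if (spikes_mean < 0 || noise_rate < 0) stop("rates must be non-negative")
  if (n_events < 0 || n_modulated < 0) stop("counts must be non-negative")
  if (min(on_dwell$mean, off_dwell$mean) < 2 * time_resolution) {
    warning("dwell mean below twice the time resolution; ",
            "bursts may be unresolvable")
  }
  structure(
    list(duration = duration, n_units = n_units, on_dwell = on_dwell,
         off_dwell = off_dwell, recruit_prob = recruit_prob,
         spikes_mean = spikes_mean, noise_rate = noise_rate,
         evoked_kernel = evoked_kernel, n_events = n_events,
         n_modulated = n_modulated, optotag_spec = optotag_spec,
         seed = as.integer(seed), time_resolution = time_resolution),
    class = "synth_config"
  )
}

#' Specify an evoked-rate kernel
#'
#' `alpha` is `amplitude * (t/peak_time) * exp(1 - t/peak_time)` after
#' `onset_delay` (peak `amplitude` Hz at `peak_time` s); `boxcar` is a flat
#' `amplitude` Hz for `width` s after `onset_delay`.
#'
#' @param shape `"alpha"` or `"boxcar"`.
#' @param amplitude Peak rate added, Hz.
#' @param peak_time Alpha-kernel time-to-peak, seconds.
#' @param onset_delay Delay from event onset to kernel start, seconds.
#' @param width Boxcar width, seconds.
#' @return Kernel spec list.
#' @export
evoked_kernel <- function(shape = c("alpha", "boxcar"), amplitude = 6,
                          peak_time = 0.65, onset_delay = 0, width = 0.5) {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (peak_time <= 0 || width <= 0 || onset_delay < 0) {
    stop("kernel times must be positive (delay non-negative)")
  }
  list(shape = shape, amplitude = amplitude, peak_time = peak_time,
       onset_delay = onset_delay, width = width)
}

#' Specify an optotagging protocol
#'
#' Default protocol: 10 pulses of 473-nm light at 2 Hz with a 10-ms pulse
#' width. Tagged units answer each pulse with probability `reliability`, at a
#' latency `|Normal(4 ms, jitter)|` truncated to `(0, 10 ms]`.
#'
#' @param n_tagged Number of light-responsive units.
#' @param reliability Per-pulse response probability.
#' @param jitter_ms Latency jitter s.d., milliseconds.
#' @param n_pulses Pulse count.
#' @param pulse_rate_hz Pulse rate, Hz.
#' @param pulse_width_ms Pulse width, milliseconds.
#' @return Optotag spec list.
#' @export
optotag_spec <- function(n_tagged = 13, reliability = 1, jitter_ms = 1,
                         n_pulses = 10, pulse_rate_hz = 2,
                         pulse_width_ms = 10) {
  if (reliability < 0 || reliability > 1) {
    stop("reliability must be in [0, 1]")
  }
  if (n_tagged < 0 || n_pulses < 1) stop("invalid counts")
  list(n_tagged = n_tagged, reliability = reliability,
       jitter_ms = jitter_ms, n_pulses = n_pulses,
       pulse_rate_hz = pulse_rate_hz, pulse_width_ms = pulse_width_ms)
}

draw_state_intervals <- function(config) {
  dur <- config$duration
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  t <- 0; state <- "off"
  # draw in blocks for speed
  while (t < dur) {
    n_blk <- 64
    d_off <- draw_dwells(config$off_dwell, n_blk)
    d_on <- draw_dwells(config$on_dwell, n_blk)
    for (i in seq_len(n_blk)) {
      d <- if (state == "off") d_off[i] else d_on[i]
      end <- min(t + d, dur)
      starts <- c(starts, t); ends <- c(ends, end); states <- c(states, state)
      t <- end
      state <- if (state == "off") "on" else "off"
      if (t >= dur) break
    }
  }
  data.frame(start = starts, end = ends, state = states,
             stringsAsFactors = FALSE)
}

simulate_population_impl <- function(config) {
  intervals <- draw_state_intervals(config)
  bursts <- intervals[intervals$state == "on", , drop = FALSE]
  uids <- sprintf("u%02d", seq_len(config$n_units))
  spikes <- stats::setNames(vector("list", config$n_units), uids)
  for (u in uids) spikes[[u]] <- numeric(0)
  recruited <- vector("list", nrow(bursts))
  if (nrow(bursts) > 0) {
    for (b in seq_len(nrow(bursts))) {
      rec <- uids[stats::runif(config$n_units) < config$recruit_prob]
      recruited[[b]] <- rec
      if (length(rec)) {
        counts <- 1 + stats::rpois(length(rec), config$spikes_mean)
        for (k in seq_along(rec)) {
          spikes[[rec[k]]] <- c(
            spikes[[rec[k]]],
            stats::runif(counts[k], bursts$start[b], bursts$end[b])
          )
        }
      }
    }
  }
  if (config$noise_rate > 0) {
    for (u in uids) {
      n_noise <- stats::rpois(1, config$noise_rate * config$duration)
      spikes[[u]] <- c(spikes[[u]], stats::runif(n_noise, 0, config$duration))
    }
  }
  sts <- suppressMessages(
    spike_train_set(lapply(spikes, sort), 0, config$duration,
                    meta = list(generator = "simulate_population",
                                seed = config$seed))
  )
  gt <- list(state_intervals = intervals, recruited = recruited,
             modulated_units = character(0), tagged_units = character(0))
  list(spikes = sts, ground_truth = gt)
}

#' Simulate a bursting population recording
#'
#' Latent on/off alternation is drawn from the configured dwell
#' distributions (tiling `[0, duration]`); during each "on" interval every
#' unit is recruited independently with `recruit_prob` and a recruited unit
#' places `1 + Poisson(spikes_mean)` spikes uniformly within the burst.
#' Every unit additionally fires homogeneous Poisson noise at `noise_rate`
#' over the whole recording (superposition).
#'
#' @param config A [synth_config()].
#' @return List with elements `spikes` (a [spike_train_set()]) and
#'   `ground_truth` (state intervals, per-burst recruited unit sets,
#'   modulated/tagged unit sets).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

place_events <- function(n, duration, min_sep = 4, edge_guard = 2) {
  # uniform placement conditional on all gaps >= min_sep, via the exact
  # spacing transform: subtract the mandatory gaps, drop n sorted uniforms
  # into the remaining free length, then add the gaps back
  span <- duration - 2 * edge_guard
  free <- span - (n - 1) * min_sep
  if (free < 0) {
    stop("cannot place ", n, " events with separation >= ", min_sep,
         " s inside ", duration, " s")
  }
  u <- sort(stats::runif(n, 0, free))
  edge_guard + u + (seq_len(n) - 1) * min_sep
}

draw_evoked_times <- function(kernel, onset, n_draw_cap = Inf) {
  if (kernel$shape == "alpha") {
    # rate(t) = A * (t/tau) * exp(1 - t/tau): an inhomogeneous Poisson
    # process with total mass A*e*tau and normalized density Gamma(2, tau)
    lam <- kernel$amplitude * exp(1) * kernel$peak_time
    n <- stats::rpois(1, lam)
    onset + kernel$onset_delay +
      stats::rgamma(n, shape = 2, scale = kernel$peak_time)
  } else {
    n <- stats::rpois(1, kernel$amplitude * kernel$width)
    onset + kernel$onset_delay + stats::runif(n, 0, kernel$width)
  }
}

#' Simulate a stimulus session (bursting background + evoked responses)
#'
#' Events are placed uniformly at random with a minimum separation of 4 s
#' and at least 2 s from the recording edges. The first `n_modulated` units
#' receive additional inhomogeneous Poisson spikes from the configured
#' evoked kernel after each event onset (superposition on top of the
#' bursting background).
#'
#' @param config A [synth_config()] with `evoked_kernel` and `n_events` set.
#' @return List with `spikes`, `events` (an [event_series()]) and
#'   `ground_truth` (with `modulated_units` filled in).
#' @export
simulate_stimulus_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(config$evoked_kernel)) stop("config$evoked_kernel must be set")
  if (config$n_events < 1) stop("config$n_events must be at least 1")
  withr::with_seed(config$seed, {
    base <- simulate_population_impl(config)
    onsets <- place_events(config$n_events, config$duration)
    uids <- base$spikes$unit_ids
    mod_units <- utils::head(uids, config$n_modulated)
    if (config$evoked_kernel$amplitude > 0 && length(mod_units)) {
      for (u in mod_units) {
        extra <- unlist(lapply(onsets, function(e) {
          draw_evoked_times(config$evoked_kernel, e)
        }))
        extra <- extra[extra <= config$duration]
        base$spikes$spikes[[u]] <- sort(c(base$spikes$spikes[[u]], extra))
      }
      base$ground_truth$modulated_units <- mod_units
    }
    events <- event_series(onsets, label = "whisker", durations = 2)
    list(spikes = base$spikes, events = events,
         ground_truth = base$ground_truth)
  })
}

#' Simulate an optotagging light protocol
#'
#' Light pulses follow the configured protocol (default ten 10-ms pulses at
#' 2 Hz). Each tagged unit emits one evoked spike per pulse with probability
#' `reliability`, at a latency drawn as `|Normal(4 ms, jitter)|` truncated
#' to `(0, 10 ms]`; untagged units have no pulse-locked response beyond the
#' bursting background.
#'
#' @param config A [synth_config()] with `optotag_spec` set.
#' @param pulse_start Time of the first pulse, seconds.
#' @return List with `spikes`, `events` (label `"light_473"`) and
#'   `ground_truth` (with `tagged_units` filled in).
#' @export
simulate_light_protocol <- function(config, pulse_start = 1) {
  stopifnot(inherits(config, "synth_config"))
  sp <- config$optotag_spec
  if (is.null(sp)) stop("config$optotag_spec must be set")
  withr::with_seed(config$seed, {
    base <- simulate_population_impl(config)
    onsets <- pulse_start + (seq_len(sp$n_pulses) - 1) / sp$pulse_rate_hz
    if (max(onsets) + 0.02 > config$duration) {
      stop("recording too short for the pulse protocol")
    }
    uids <- base$spikes$unit_ids
    tagged <- utils::head(uids, sp$n_tagged)
    for (u in tagged) {
      answered <- stats::runif(sp$n_pulses) < sp$reliability
      lat <- vapply(which(answered), function(i) {
        repeat {
          l <- abs(stats::rnorm(1, 0.004, sp$jitter_ms / 1000))
          if (l > 0 && l <= 0.010) return(l)
        }
      }, numeric(1))
      base$spikes$spikes[[u]] <- sort(c(base$spikes$spikes[[u]],
                                        onsets[answered] + lat))
    }
    base$ground_truth$tagged_units <- tagged
    events <- event_series(onsets, label = "light_473",
                           durations = sp$pulse_width_ms / 1000)
    list(spikes = base$spikes, events = events,
         ground_truth = base$ground_truth)
  })
}

#' Simulate an operant-conditioning cohort
#'
#' Each session has 150 blue (473-nm) and 150 red (635-nm) trials. Learners'
#' expected blue-lick totals rise linearly across days (from `blue_start` by
#' `learn_slope` per day) while red totals stay flat at `base_licks`;
#' non-learners keep both flat at `base_licks`. Per-trial lick counts are
#' Poisson draws around the session mean.
#'
#' @param n_animals Cohort size.
#' @param days Training days per animal.
#' @param learner_flags Logical vector (recycled) marking learners.
#' @param seed Integer seed.
#' @param trials_per_colour Trials of each colour per session (default 150).
#' @param base_licks Expected per-session lick total for a flat colour.
#' @param blue_start Learner expected blue total on day 1.
#' @param learn_slope Learner expected blue-total increase per day.
#' @return List (one element per animal) of lists of [behavior_session()]s.
#' @export
simulate_behavior_cohort <- function(n_animals, days, learner_flags,
                                     seed = 1, trials_per_colour = 150,
                                     base_licks = 40, blue_start = 10,
                                     learn_slope = 6) {
  if (days < 1) stop("days must be at least 1")
  if (n_animals < 1) stop("n_animals must be at least 1")
  learner_flags <- rep_len(as.logical(learner_flags), n_animals)
  withr::with_seed(seed, {
    lapply(seq_len(n_animals), function(a) {
      lapply(seq_len(days), function(d) {
        blue_mean <- if (learner_flags[a]) {
          blue_start + learn_slope * (d - 1)
        } else {
          base_licks
        }
        trials <- data.frame(
          trial = seq_len(2 * trials_per_colour),
          colour = sample(rep(c(473, 635), each = trials_per_colour)),
          stringsAsFactors = FALSE
        )
        trials$licks <- ifelse(
          trials$colour == 473,
          stats::rpois(nrow(trials), blue_mean / trials_per_colour),
          stats::rpois(nrow(trials), base_licks / trials_per_colour)
        )
        trials$rewarded <- trials$colour == 473 & trials$licks > 0
        behavior_session(sprintf("A%d", a), d, trials)
      })
    })
  })
}

#' Deterministic worked-example behaviour cohort
#'
#' Nine animals over 15 days: animals A1-A8 produce `10 + 6 * (day - 1)`
#' blue licks and 40 red licks per session; animal A9 produces 40 of each.
#' Session totals are laid out as one lick on the first `total` trials of
#' each colour, so the cohort is fully deterministic.
#'
#' @return List (one element per animal) of lists of [behavior_session()]s.
#' @export
fixture_F1 <- function() {
  build_session <- function(animal, day, blue_total, red_total) {
    stopifnot(blue_total <= 150, red_total <= 150)
    trials <- data.frame(
      trial = 1:300,
      colour = rep(c(473, 635), each = 150),
      licks = c(as.integer(1:150 <= blue_total),
                as.integer(1:150 <= red_total)),
      stringsAsFactors = FALSE
    )
    trials$rewarded <- trials$colour == 473 & trials$licks > 0
    behavior_session(animal, day, trials)
  }
  cohort <- lapply(1:8, function(a) {
    lapply(1:15, function(d) {
      build_session(sprintf("A%d", a), d, 10 + 6 * (d - 1), 40)
    })
  })
  c(cohort, list(lapply(1:15, function(d) build_session("A9", d, 40, 40))))
}
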