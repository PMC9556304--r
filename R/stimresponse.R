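# Stimulus-evoked modulation: trial alignment of z-scored rates, paired
# Wilcoxon pre/post testing on per-trial spike counts, latency-to-peak of
# the trial-averaged response, and a randomized-timestamp null control.

#' Align binned rates to event onsets
#'
#' Builds a trials x units x lags tensor of rates on a lag grid snapped to
#' the rate step (`seq(-pre, post, by = step)`, inclusive). The rate value
#' at a lag is the bin whose centre is nearest that time. Events whose
#' window does not fit inside the recording are dropped with a count.
#'
#' @param rates A `binned_rates` object (typically z-scored).
#' @param events An [event_series()].
#' @param pre,post Window before/after onset, seconds.
#' @return An object of class `trial_tensor`: `z` (trials x units x lags
#'   array), `lags`, `units`, `n_dropped`.
#' @export
align_trials <- function(rates, events, pre = 1, post = 2) {
  stopifnot(inherits(rates, "binned_rates"), inherits(events, "event_series"))
  lags <- seq(-pre, post, by = rates$step)
  n_bins <- ncol(rates$matrix)
  centre0 <- rates$t_start + rates$bin_width / 2
  idx_of <- function(t) as.integer(round((t - centre0) / rates$step)) + 1L
  usable <- logical(length(events$onsets))
  idx_mat <- matrix(NA_integer_, length(events$onsets), length(lags))
  for (e in seq_along(events$onsets)) {
    ii <- idx_of(events$onsets[e] + lags)
    if (all(ii >= 1 & ii <= n_bins)) {
      usable[e] <- TRUE
      idx_mat[e, ] <- ii
    }
  }
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(n_dropped, " event(s) dropped (window outside recording)")
  }
  if (!any(usable)) stop("no usable events inside the recording")
  keep <- which(usable)
  z <- array(NA_real_,
             dim = c(length(keep), nrow(rates$matrix), length(lags)),
             dimnames = list(NULL, rownames(rates$matrix), NULL))
  for (k in seq_along(keep)) {
    z[k, , ] <- rates$matrix[, idx_mat[keep[k], ], drop = FALSE]
  }
  structure(
    list(z = z, lags = lags, pre = pre, post = post, step = rates$step,
         units = rownames(rates$matrix), n_dropped = n_dropped),
    class = "trial_tensor"
  )
}

count_in_window <- function(sp, lo, hi, open_left = TRUE) {
  # count spikes in (lo, hi] (open_left) or [lo, hi)
  if (!length(sp)) return(numeric(length(lo)))
  if (open_left) {
    findInterval(hi, sp) - findInterval(lo, sp)
  } else {
    findInterval(hi, sp, left.open = TRUE) -
      findInterval(lo, sp, left.open = TRUE)
  }
}

#' Test stimulus modulation of each unit
#'
#' Per unit, the paired samples are per-trial spike counts in
#' `(onset, onset + post]` versus `[onset - pre, onset)`, compared with a
#' two-sided Wilcoxon signed-rank test (exact when there are at most 25
#' non-zero differences and no ties, normal approximation with continuity
#' correction otherwise; zero differences dropped). With
#' `direction = "increase"` (default) a unit is flagged modulated when
#' `p < alpha` AND the median difference is positive; `"two.sided"` flags on
#' the p-value alone.
#'
#' @param spikes A [spike_train_set()].
#' @param events An [event_series()].
#' @param pre,post Windows in seconds (defaults 1 and 1).
#' @param alpha Significance threshold (default 0.05).
#' @param direction `"increase"` or `"two.sided"`.
#' @return A data.frame of class `modulation_result` with per-unit columns
#'   `unit`, `n_trials`, `p_value`, `median_diff`, `modulated`.
#' @export
modulation_test <- function(spikes, events, pre = 1, post = 1, alpha = 0.05,
                            direction = c("increase", "two.sided")) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(events, "event_series"))
  direction <- match.arg(direction)
  on <- events$onsets
  ok <- on - pre >= spikes$t_start & on + post <= spikes$t_stop
  if (sum(!ok) > 0) {
    message(sum(!ok), " event(s) dropped (pre/post window outside recording)")
  }
  on <- on[ok]
  if (!length(on)) stop("no usable events")
  if (length(on) < 10) {
    warning("fewer than 10 usable events; modulation test is weak")
  }
  res <- lapply(seq_along(spikes$unit_ids), function(u) {
    sp <- spikes$spikes[[u]]
    post_n <- count_in_window(sp, on, on + post, open_left = TRUE)
    pre_n <- count_in_window(sp, on - pre, on, open_left = FALSE)
    d <- post_n - pre_n
    nz <- d[d != 0]
    if (!length(nz)) {
      p <- 1
    } else {
      use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
      p <- suppressWarnings(
        stats::wilcox.test(nz, mu = 0, exact = use_exact,
                           correct = TRUE)$p.value
      )
    }
    data.frame(unit = spikes$unit_ids[u], n_trials = length(on),
               p_value = p, median_diff = stats::median(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$modulated <- if (direction == "increase") {
    out$p_value < alpha & out$median_diff > 0
  } else {
    out$p_value < alpha
  }
  structure(out, class = c("modulation_result", "data.frame"),
            alpha = alpha, pre = pre, post = post, direction = direction)
}

#' Latency to peak of the trial-averaged response
#'
#' Per unit, the lag of the maximum of the trial-averaged z trace within
#' `(0, window]` after onset; resolution equals the rate step. An all-equal
#' trace yields the earliest positive lag with a degenerate flag.
#'
#' @param tensor An [align_trials()] result whose post window covers
#'   `window`.
#' @param window Search window after onset, seconds (default 2).
#' @return data.frame with `unit`, `latency_s`, `degenerate`.
#' @export
latency_to_peak <- function(tensor, window = 2) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (max(tensor$lags) < window - 1e-9) {
    stop("tensor post window (", max(tensor$lags),
         " s) shorter than the latency window (", window, " s)")
  }
  sel <- which(tensor$lags > 1e-12 & tensor$lags <= window + 1e-12)
  mean_tr <- apply(tensor$z, c(2, 3), mean)   # units x lags
  out <- lapply(seq_along(tensor$units), function(u) {
    tr <- mean_tr[u, sel]
    degenerate <- max(tr) - min(tr) < .Machine$double.eps^0.5
    data.frame(unit = tensor$units[u],
               latency_s = tensor$lags[sel[which.max(tr)]],
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Randomized-timestamp control events
#'
#' Same event count as the input, onsets drawn uniformly over the
#' admissible range (a guard band of `pre + post` inside the recording
#' bounds), seeded. Intended to be run through the same alignment/testing
#' path as the real events as a null control.
#'
#' @param events An [event_series()].
#' @param t_start,t_stop Recording bounds, seconds.
#' @param seed Integer seed.
#' @param pre,post Analysis windows that must fit around every control
#'   event, seconds.
#' @return An [event_series()] labelled `"<label>_control"`.
#' @export
random_timestamp_control <- function(events, t_start, t_stop, seed,
                                     pre = 1, post = 2) {
  stopifnot(inherits(events, "event_series"))
  guard <- pre + post
  lo <- t_start + guard
  hi <- t_stop - guard
  if (hi <= lo) stop("admissible range empty for the given guard band")
  withr::with_seed(seed, {
    event_series(sort(stats::runif(length(events$onsets), lo, hi)),
                 label = paste0(events$label, "_control"),
                 durations = events$durations)
  })
}
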