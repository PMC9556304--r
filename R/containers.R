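#' Construct a spike-train set
#'
#' The universal input container of the pipeline: per-unit spike-time vectors
#' (seconds) within a recording interval `[t_start, t_stop]`. Spike times are
#' sorted on construction; duplicate times closer than one sample period are
#' collapsed (recordings are discretely sampled, so two "spikes" inside one
#' sample period are the same event).
#'
#' @param spikes Named list, one ascending numeric vector of spike times
#'   (seconds) per unit. Names are unit ids; an empty vector is a valid
#'   (silent) unit.
#' @param t_start,t_stop Recording bounds in seconds (`t_start < t_stop`).
#' @param sample_period Seconds; spikes of one unit closer than this are
#'   collapsed to one. Default `1/30000` (30-kHz acquisition).
#' @param meta Free-form list of tags (acquisition rate label etc.).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, t_start, t_stop,
                            sample_period = 1 / 30000, meta = list()) {
  stopifnot(is.list(spikes), is.numeric(t_start), is.numeric(t_stop))
  if (!(t_start < t_stop)) {
    stop("t_start (", t_start, ") must be strictly less than t_stop (", t_stop, ")")
  }
  if (length(spikes) > 0 && is.null(names(spikes))) {
    names(spikes) <- paste0("u", seq_along(spikes))
  }
  n_collapsed <- 0L
  spikes <- lapply(spikes, function(sp) {
    sp <- sort(as.numeric(sp))
    if (length(sp) > 1) {
      keep <- c(TRUE, diff(sp) >= sample_period)
      n_collapsed <<- n_collapsed + sum(!keep)
      sp <- sp[keep]
    }
    sp
  })
  bad <- vapply(spikes, function(sp) {
    length(sp) > 0 && (min(sp) < t_start || max(sp) > t_stop)
  }, logical(1))
  if (any(bad)) {
    stop("spike times outside [t_start, t_stop] for unit(s): ",
         paste(names(spikes)[bad], collapse = ", "))
  }
  if (n_collapsed > 0) {
    message(n_collapsed, " spike(s) within one sample period collapsed")
  }
  meta$n_collapsed <- n_collapsed
  structure(
    list(unit_ids = names(spikes), spikes = spikes,
         t_start = as.numeric(t_start), t_stop = as.numeric(t_stop),
         meta = meta),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat("<spike_train_set> ", length(x$unit_ids), " units, ", n_sp,
      " spikes, [", x$t_start, ", ", x$t_stop, "] s\n", sep = "")
  invisible(x)
}

#' Number of units in a spike-train set
#' @param x A `spike_train_set`.
#' @return Integer unit count.
#' @export
n_units <- function(x) length(x$unit_ids)

#' Construct an event series
#'
#' Labelled stimulus/trial timestamps: whisker deflections, light pulses,
#' trial starts. Onsets must be ascending; intervals are half-open
#' `[onset, onset + duration)`.
#'
#' @param onsets Ascending numeric vector of onset times (seconds).
#' @param label Single category label (e.g. `"whisker"`, `"light_473"`).
#' @param durations Per-event durations (seconds); recycled if scalar.
#' @param attributes Optional data.frame of per-event fields (one row per
#'   event).
#' @return An object of class `event_series`.
#' @export
event_series <- function(onsets, label = "custom", durations = 0,
                         attributes = NULL) {
  onsets <- as.numeric(onsets)
  if (is.unsorted(onsets)) {
    first_bad <- which(diff(onsets) < 0)[1] + 1L
    stop("onsets must be ascending; first offending row: ", first_bad)
  }
  durations <- rep_len(as.numeric(durations), length(onsets))
  if (any(durations < 0)) stop("durations must be non-negative")
  if (!is.null(attributes)) {
    stopifnot(is.data.frame(attributes), nrow(attributes) == length(onsets))
  }
  structure(
    list(label = as.character(label)[1], onsets = onsets,
         durations = durations, attributes = attributes),
    class = "event_series"
  )
}

#' @export
print.event_series <- function(x, ...) {
  cat("<event_series> '", x$label, "', ", length(x$onsets), " events\n",
      sep = "")
  invisible(x)
}

#' Number of events in an event series
#' @param x An `event_series`.
#' @return Integer event count.
#' @export
n_events <- function(x) length(x$onsets)

#' Construct a behaviour session
#'
#' One operant-conditioning training session for one animal: per-trial
#' stimulation colour (473-nm blue vs 635-nm red), lick count, and reward
#' flag.
#'
#' @param animal Animal id.
#' @param day Training-day index (1-based).
#' @param trials data.frame with columns `trial`, `colour` (473 or 635),
#'   `licks` (non-negative integer), `rewarded` (logical).
#' @return An object of class `behavior_session`.
#' @export
behavior_session <- function(animal, day, trials) {
  stopifnot(is.data.frame(trials),
            all(c("trial", "colour", "licks", "rewarded") %in% names(trials)))
  if (!all(trials$colour %in% c(473, 635))) {
    stop("colour must be 473 or 635 (stimulation wavelength in nm)")
  }
  if (any(trials$licks < 0) || any(trials$licks != round(trials$licks))) {
    stop("lick counts must be non-negative integers")
  }
  structure(
    list(animal = as.character(animal), day = as.integer(day),
         trials = trials,
         total_blue_licks = sum(trials$licks[trials$colour == 473]),
         total_red_licks = sum(trials$licks[trials$colour == 635])),
    class = "behavior_session"
  )
}

#' @export
print.behavior_session <- function(x, ...) {
  cat("<behavior_session> animal ", x$animal, ", day ", x$day, ", ",
      nrow(x$trials), " trials (blue licks ", x$total_blue_licks,
      ", red licks ", x$total_red_licks, ")\n", sep = "")
  invisible(x)
}
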