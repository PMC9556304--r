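# Operant-conditioning analysis: per-session preference index, per-animal
# trajectories, and the cohort learning-success criterion.

#' Preference index between blue- and red-trial lick counts
#'
#' `(blue - red) / (blue + red)` over a session's lick totals during
#' 473-nm (blue) versus 635-nm (red) stimulation. Undefined (returned as
#' `NA`) when both counts are zero; undefined days are excluded from
#' trajectories rather than treated as 0.
#'
#' @param blue_licks,red_licks Non-negative integer lick totals
#'   (vectorized).
#' @return Numeric score(s) in `[-1, 1]`, `NA` where both counts are zero.
#' @export
preference_index <- function(blue_licks, red_licks) {
  if (any(blue_licks < 0) || any(red_licks < 0)) {
    stop("lick counts must be non-negative")
  }
  tot <- blue_licks + red_licks
  ifelse(tot == 0, NA_real_, (blue_licks - red_licks) / tot)
}

#' Per-day preference trajectories of a cohort
#'
#' Sums blue and red lick counts within each session and applies
#' [preference_index()] per (animal, day).
#'
#' @param sessions List of [behavior_session()] objects (or a list of
#'   per-animal session lists, as the simulators return).
#' @return A data.frame of class `preference_trajectory` with columns
#'   `animal`, `day`, `blue_licks`, `red_licks`, `preference`, `defined`,
#'   sorted by animal then day.
#' @export
session_preferences <- function(sessions) {
  if (length(sessions) && !inherits(sessions[[1]], "behavior_session")) {
    sessions <- unlist(sessions, recursive = FALSE)
  }
  stopifnot(all(vapply(sessions, inherits, logical(1), "behavior_session")))
  out <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(animal = s$animal, day = s$day,
               blue_licks = s$total_blue_licks,
               red_licks = s$total_red_licks, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(out[, c("animal", "day")])) {
    stop("duplicate (animal, day) session")
  }
  out <- out[order(out$animal, out$day), ]
  rownames(out) <- NULL
  out$preference <- preference_index(out$blue_licks, out$red_licks)
  out$defined <- !is.na(out$preference)
  structure(out, class = c("preference_trajectory", "data.frame"))
}

#' Cohort learning-success criterion
#'
#' An animal is a learner when its trajectory contains a run of at least
#' `consecutive` days whose preference scores are all defined and strictly
#' above `threshold`. Undefined days break runs. The cohort rate is
#' reported rounded to the nearest percent; the raw fraction is retained.
#'
#' @param trajectories A [session_preferences()] data.frame.
#' @param threshold Preference threshold (default 0.2, strict inequality).
#' @param consecutive Required consecutive days (default 2).
#' @return List with `flags` (named per-animal logical),
#'   `first_success_day` (named integer, `NA` for non-learners),
#'   `rate_percent` (rounded) and `rate_fraction`.
#' @export
learning_success <- function(trajectories, threshold = 0.2,
                             consecutive = 2) {
  stopifnot(inherits(trajectories, "data.frame"))
  if (nrow(trajectories) == 0) stop("empty cohort")
  animals <- unique(trajectories$animal)
  flags <- stats::setNames(logical(length(animals)), animals)
  first_day <- stats::setNames(rep(NA_integer_, length(animals)), animals)
  for (a in animals) {
    tr <- trajectories[trajectories$animal == a, ]
    tr <- tr[order(tr$day), ]
    hit <- tr$defined & tr$preference > threshold
    # consecutive calendar days, not merely consecutive rows
    run <- 0L
    for (i in seq_len(nrow(tr))) {
      contiguous <- i > 1 && tr$day[i] == tr$day[i - 1] + 1L
      run <- if (hit[i]) { if (contiguous) run + 1L else 1L } else 0L
      if (run >= consecutive) {
        flags[a] <- TRUE
        first_day[a] <- tr$day[i]
        break
      }
    }
  }
  frac <- mean(flags)
  list(flags = flags, first_success_day = first_day,
       rate_percent = round(100 * frac), rate_fraction = frac)
}
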