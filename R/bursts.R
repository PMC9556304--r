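# Burst tables and statistics from a decoded state path. Runs shorter than
# min_run bins are merged into a flanking state; run duration follows the
# (k - 1) * step convention, which compensates the ~one-bin outward smear
# that 200-ms windows on 100-ms steps produce around a true burst.

#' Extract burst and inter-burst intervals from a state path
#'
#' Maximal runs of identical state are tabulated. Interior runs shorter
#' than `min_run` bins are merged into a flanking run (the shorter
#' neighbour first, ties to the left), which suppresses single-bin flicker;
#' boundary runs are exempt since the recording edge truncates them. A run of
#' k bins spans the centres of its first and last bin, so its duration is
#' `(k - 1) * step`. Runs touching either recording boundary are flagged
#' non-interior and excluded from duration statistics downstream.
#'
#' @param path A [viterbi()] result with bin geometry attached.
#' @param min_run Minimum run length in bins (default 2).
#' @return A data.frame of class `burst_table` with columns `start_s`,
#'   `end_s`, `duration_s`, `state`, `interior`.
#' @export
label_bursts <- function(path, min_run = 2) {
  stopifnot(inherits(path, "state_path"))
  if (is.null(path$bin_left_edges)) {
    stop("state path carries no bin geometry; decode an obs_sequence")
  }
  states <- path$states
  # iterative merge of sub-minimum runs into a flanking state
  repeat {
    r <- rle(states)
    # boundary runs are truncated by the recording edge, so their observed
    # length says nothing about their true length: exempt from merging
    short <- setdiff(which(r$lengths < min_run),
                     c(1L, length(r$lengths)))
    if (length(r$lengths) <= 1 || !length(short)) break
    i <- short[which.min(r$lengths[short])][1]
    left_len <- if (i > 1) r$lengths[i - 1] else Inf
    right_len <- if (i < length(r$lengths)) r$lengths[i + 1] else Inf
    take <- if (left_len <= right_len) i - 1 else i + 1
    r$values[i] <- r$values[take]
    states <- inverse.rle(r)
  }
  r <- rle(states)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  centre <- path$bin_left_edges + path$bin_width / 2
  tab <- data.frame(
    start_s = centre[starts_idx],
    end_s = centre[ends_idx],
    duration_s = (r$lengths - 1) * path$step,
    state = r$values,
    interior = starts_idx > 1 & ends_idx < length(states),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("burst_table", "data.frame"),
            step = path$step, bin_width = path$bin_width,
            min_run = min_run)
}

#' Summary statistics of detected bursts
#'
#' Duration and inter-burst-interval means are computed over interior runs
#' only (boundary-truncated runs are biased). Recruitment is the mean over
#' interior bursts of the fraction of units with at least one spike inside
#' the burst interval; spikes-per-burst is the mean spike count over
#' recruited (unit, burst) pairs only, so the two statistics are not
#' redundant.
#'
#' @param bursts A [label_bursts()] table.
#' @param spikes The [spike_train_set()] the path was derived from.
#' @return An object of class `burst_stats`: `n_bursts`, `mean_duration_s`,
#'   `median_duration_s`, `mean_ibi_s`, `mean_spikes_per_burst`,
#'   `recruitment`, `defined`.
#' @export
burst_statistics <- function(bursts, spikes) {
  stopifnot(inherits(bursts, "burst_table"),
            inherits(spikes, "spike_train_set"))
  on_int <- bursts[bursts$state == "on" & bursts$interior, , drop = FALSE]
  off_int <- bursts[bursts$state == "off" & bursts$interior, , drop = FALSE]
  if (nrow(on_int) == 0) {
    return(structure(list(n_bursts = 0L, mean_duration_s = NA_real_,
                          median_duration_s = NA_real_, mean_ibi_s = NA_real_,
                          mean_spikes_per_burst = NA_real_,
                          recruitment = NA_real_, defined = FALSE),
                     class = "burst_stats"))
  }
  counts <- matrix(0, nrow = length(spikes$unit_ids), ncol = nrow(on_int))
  for (u in seq_along(spikes$unit_ids)) {
    sp <- spikes$spikes[[u]]
    if (!length(sp)) next
    # spikes inside the closed burst interval [start, end]
    counts[u, ] <- findInterval(on_int$end_s, sp) -
      findInterval(on_int$start_s, sp, left.open = TRUE)
  }
  fired <- counts > 0
  recruitment <- mean(colMeans(fired))
  spk_rec <- counts[fired]
  structure(
    list(n_bursts = nrow(on_int),
         mean_duration_s = mean(on_int$duration_s),
         median_duration_s = stats::median(on_int$duration_s),
         mean_ibi_s = if (nrow(off_int)) mean(off_int$duration_s) else NA_real_,
         mean_spikes_per_burst = if (length(spk_rec)) mean(spk_rec) else NA_real_,
         recruitment = recruitment, defined = TRUE),
    class = "burst_stats"
  )
}

#' @export
print.burst_stats <- function(x, ...) {
  if (!x$defined) {
    cat("<burst_stats> no interior bursts; statistics undefined\n")
    return(invisible(x))
  }
  cat("<burst_stats> ", x$n_bursts, " interior bursts\n",
      "  mean duration: ", format(x$mean_duration_s, digits = 4), " s\n",
      "  mean inter-burst interval: ", format(x$mean_ibi_s, digits = 4),
      " s\n",
      "  spikes per recruited (unit, burst): ",
      format(x$mean_spikes_per_burst, digits = 4), "\n",
      "  recruitment: ", format(x$recruitment, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Run the full burst-segmentation pipeline
#'
#' Convenience wrapper: 200-ms/100-ms sliding-window rates, per-unit
#' z-scoring, population binarization at z = 0, Baum-Welch from the default
#' initial guesses, Viterbi decoding, run labelling, and burst statistics.
#'
#' @param spikes A [spike_train_set()].
#' @param bin_width,step Bin geometry, seconds.
#' @param threshold Binarization threshold, z-units.
#' @param init Initial `hmm_spec`.
#' @param tol,max_iter Baum-Welch convergence controls.
#' @param min_run Minimum run length in bins.
#' @return List with `rates`, `obs`, `model`, `path`, `bursts`, `stats`.
#' @export
burst_pipeline <- function(spikes, bin_width = 0.2, step = 0.1,
                           threshold = 0, init = hmm_init_default(),
                           tol = 1e-6, max_iter = 500, min_run = 2) {
  rates <- suppressWarnings(
    zscore_rates(bin_firing_rates(spikes, bin_width, step))
  )
  obs <- binarize_population(rates, threshold)
  model <- baum_welch(obs, init = init, tol = tol, max_iter = max_iter)
  path <- viterbi(obs, model)
  bursts <- label_bursts(path, min_run = min_run)
  list(rates = rates, obs = obs, model = model, path = path,
       bursts = bursts, stats = burst_statistics(bursts, spikes))
}
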