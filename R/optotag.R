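# Optotagging: classify light-responsive units from pulse-aligned spiking.
# A unit answers a pulse when it has at least one spike within the latency
# window after pulse onset; the window is half-open at the onset (a spike
# exactly at onset is excluded -- it is indistinguishable from a light
# artifact) and closed at the upper bound ("within 10 ms" is inclusive).

#' Classify optotagged (light-responsive) units
#'
#' Per pulse, a unit responds iff it has >= 1 spike in
#' `(onset, onset + max_latency]`; reliability is the fraction of pulses
#' answered, and a unit is responsive when reliability is at or above
#' `min_reliability` ("70% or more" is inclusive). Median first-spike
#' latency is reported over answered pulses only.
#'
#' @param spikes A [spike_train_set()].
#' @param pulses An [event_series()] of light-pulse onsets (>= 1 pulse,
#'   non-overlapping at the latency-window scale).
#' @param max_latency Response window after pulse onset, seconds
#'   (default 0.010).
#' @param min_reliability Reliability threshold (default 0.7, inclusive).
#' @return A data.frame of class `optotag_result` with per-unit columns
#'   `unit`, `reliability`, `median_latency_ms`, `responsive`.
#' @export
classify_optotagged <- function(spikes, pulses, max_latency = 0.010,
                                min_reliability = 0.7) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(pulses, "event_series"))
  on <- pulses$onsets
  if (!length(on)) stop("zero pulses")
  if (length(on) > 1 && any(diff(on) <= max_latency)) {
    stop("pulse windows overlap at the latency-window scale")
  }
  res <- lapply(seq_along(spikes$unit_ids), function(u) {
    sp <- spikes$spikes[[u]]
    n_resp <- 0L
    lats <- numeric(0)
    if (length(sp)) {
      # first spike strictly after onset
      first_idx <- findInterval(on, sp) + 1L
      has <- first_idx <= length(sp) & sp[pmin(first_idx, length(sp))] <=
        on + max_latency
      n_resp <- sum(has)
      lats <- sp[first_idx[has]] - on[has]
    }
    data.frame(unit = spikes$unit_ids[u],
               reliability = n_resp / length(on),
               median_latency_ms = if (n_resp) {
                 stats::median(lats) * 1000
               } else {
                 NA_real_
               },
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$responsive <- out$reliability >= min_reliability
  structure(out, class = c("optotag_result", "data.frame"),
            max_latency = max_latency, min_reliability = min_reliability,
            n_pulses = length(on))
}
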