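# Sliding-window firing rates, z-scoring, pairwise correlations and Welch
# power spectra. Bins are half-open [edge, edge + bin_width) with left edges
# at t_start + i*step; the trailing partial bin is dropped.

#' Compute sliding-window firing rates
#'
#' Entry (u, i) is the number of unit u's spikes in
#' `[edge_i, edge_i + bin_width)` divided by `bin_width` (Hz). The defaults
#' (200-ms bins sliding by 100 ms) are the geometry the burst pipeline
#' expects.
#'
#' @param spikes A [spike_train_set()].
#' @param bin_width Window width, seconds (default 0.2).
#' @param step Window slide, seconds (default 0.1); must satisfy
#'   `bin_width >= step > 0` (gaps between windows are unsupported).
#' @return An object of class `binned_rates`: units x bins matrix plus bin
#'   geometry.
#' @export
bin_firing_rates <- function(spikes, bin_width = 0.2, step = 0.1) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (step <= 0) stop("step must be positive")
  if (bin_width < step) stop("bin_width < step would leave gaps; unsupported")
  span <- spikes$t_stop - spikes$t_start
  if (span <= bin_width) stop("recording shorter than one bin")
  n_bins <- floor((span - bin_width) / step + 1e-9) + 1L
  edges <- spikes$t_start + (seq_len(n_bins) - 1) * step
  m <- matrix(0, nrow = length(spikes$unit_ids), ncol = n_bins,
              dimnames = list(spikes$unit_ids, NULL))
  for (u in seq_along(spikes$unit_ids)) {
    sp <- spikes$spikes[[u]]
    if (!length(sp)) next
    # count in [e, e+bw) = #(sp < e+bw) - #(sp < e)
    lt <- function(y) findInterval(y, sp, left.open = TRUE)
    m[u, ] <- (lt(edges + bin_width) - lt(edges)) / bin_width
  }
  structure(
    list(matrix = m, bin_width = bin_width, step = step,
         bin_left_edges = edges, t_start = spikes$t_start,
         t_stop = spikes$t_stop, zscored = FALSE),
    class = "binned_rates"
  )
}

#' @export
print.binned_rates <- function(x, ...) {
  cat("<binned_rates> ", nrow(x$matrix), " units x ", ncol(x$matrix),
      " bins (", x$bin_width, " s / ", x$step, " s)",
      if (x$zscored) ", z-scored", "\n", sep = "")
  invisible(x)
}

#' Z-score binned rates per unit
#'
#' Each unit row is centred and scaled by its sample (n-1) standard
#' deviation over the whole recording. Constant rows (silent or perfectly
#' regular units) map to all-zero rows with a warning rather than an error.
#'
#' @param rates A non-z-scored [bin_firing_rates()] result.
#' @return A `binned_rates` object with `zscored = TRUE`.
#' @export
zscore_rates <- function(rates) {
  stopifnot(inherits(rates, "binned_rates"))
  if (rates$zscored) stop("rates are already z-scored")
  m <- rates$matrix
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  const <- sdv == 0 | is.na(sdv)
  if (any(const)) {
    warning(sum(const), " constant unit row(s) mapped to zeros")
    sdv[const] <- 1
  }
  z <- (m - mu) / sdv
  z[const, ] <- 0
  rates$matrix <- z
  rates$zscored <- TRUE
  rates$constant_units <- rownames(m)[const]
  rates
}

#' Pairwise rate correlations across units
#'
#' Pearson correlation between unit rate rows. Pairs involving constant rows
#' are undefined and excluded from the off-diagonal summary.
#'
#' @param rates A `binned_rates` object (>= 2 units, >= 3 bins).
#' @param method Correlation estimator passed to [stats::cor()]
#'   (default `"pearson"`).
#' @return List with the unit x unit correlation `matrix`, `mean_offdiag`
#'   over defined pairs, `offdiag` values, and `excluded_units`.
#' @export
pairwise_correlations <- function(rates, method = "pearson") {
  stopifnot(inherits(rates, "binned_rates"))
  m <- rates$matrix
  if (ncol(m) < 3) stop("need at least 3 bins")
  sdv <- apply(m, 1, stats::sd)
  valid <- which(sdv > 0 & !is.na(sdv))
  if (length(valid) < 2) stop("fewer than 2 non-constant units")
  C <- suppressWarnings(stats::cor(t(m), method = method))
  diag(C) <- 1
  off <- C[valid, valid][upper.tri(C[valid, valid])]
  list(matrix = C, mean_offdiag = mean(off), offdiag = off,
       excluded_units = rownames(m)[setdiff(seq_len(nrow(m)), valid)])
}

#' Compare off-diagonal correlation sets between two recordings
#'
#' Two-sided Wilcoxon rank-sum test between the off-diagonal correlation
#' values of two [pairwise_correlations()] results.
#'
#' @param a,b Results of [pairwise_correlations()].
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_correlations <- function(a, b) {
  suppressWarnings(stats::wilcox.test(a$offdiag, b$offdiag))
}

#' Welch power spectral density
#'
#' Average of Hann-windowed, 50%-overlapping segment periodograms with
#' per-segment mean removal; density normalization, so the integral of the
#' PSD over frequency approximates the signal variance. The default segment
#' length is `10 * fs` samples (10 s of signal).
#'
#' @param signal Evenly sampled numeric vector.
#' @param fs Sampling rate, Hz.
#' @param segment_length Samples per segment (default `10 * fs`).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(signal, fs, segment_length = round(10 * fs),
                      overlap = 0.5) {
  n <- length(signal)
  L <- as.integer(segment_length)
  if (n < L) {
    stop("signal (", n, " samples) shorter than one segment (", L,
         "); use a smaller segment_length")
  }
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)   # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  n_f <- floor(L / 2) + 1L
  acc <- numeric(n_f)
  for (s in starts) {
    seg <- signal[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 * scale
    acc <- acc + p[seq_len(n_f)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- 2:(n_f - if (L %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(n_f) - 1) * fs / L, psd = psd)
}

#' Population-mean rate trace
#'
#' Mean over units of the (optionally z-scored) rate matrix, one value per
#' bin; the univariate signal used for binarization and spectral analysis.
#'
#' @param rates A `binned_rates` object.
#' @return Numeric vector, one value per bin.
#' @export
population_trace <- function(rates) {
  stopifnot(inherits(rates, "binned_rates"))
  colMeans(rates$matrix)
}
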