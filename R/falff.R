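#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Per region: remove the mean and linear trend, take the discrete Fourier
#' transform, and form the ratio of summed spectral amplitudes (moduli of the
#' DFT coefficients, i.e. square roots of power) inside the low-frequency
#' band to the sum over all positive frequencies up to Nyquist. The DC bin is
#' excluded from numerator and denominator; band endpoints are inclusive on
#' the discrete grid `k / (T * TR)`. Values are scale-invariant and lie in
#' `[0, 1]`.
#'
#' Note the regional approximation: fALFF is computed directly on the region
#' time course (voxelwise computation followed by within-region averaging
#' requires voxel data, which this pipeline does not ingest).
#'
#' @param ts A [roi_timeseries()] with at least 8 time points.
#' @param band Length-2 numeric, band edges in Hz within `(0, Nyquist]`.
#'   Default 0.008-0.09 Hz, the standard band for spontaneous BOLD activity.
#' @return A named numeric vector of per-region fALFF values with attribute
#'   `band`.
#' @export
compute_falff <- function(ts, band = c(0.008, 0.09)) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$tr)
  if (length(band) != 2L || !(band[1] > 0 && band[1] < band[2])) {
    abort("`band` must be (low, high) with 0 < low < high.")
  }
  if (band[2] > nyquist + 1e-12) {
    abort(sprintf("Band upper edge %g Hz exceeds Nyquist %g Hz.", band[2], nyquist))
  }
  x <- detrend_linear(ts$data)
  tt <- nrow(x)
  amps <- Mod(stats::mvfft(x))
  k <- seq_len(floor(tt / 2)) # positive frequencies, DC excluded
  freq <- k / (tt * ts$tr)
  amps <- amps[k + 1L, , drop = FALSE]
  in_band <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  denom <- colSums(amps)
  if (any(denom == 0)) {
    abort(sprintf("Constant (zero-spectrum) region(s): %s.",
                  paste(ts$region_names[denom == 0], collapse = ", ")))
  }
  vals <- colSums(amps[in_band, , drop = FALSE]) / denom
  structure(stats::setNames(as.numeric(vals), ts$region_names), band = band)
}
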