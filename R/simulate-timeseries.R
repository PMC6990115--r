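#' Specification for synthetic two-condition ROI time series
#'
#' Emulates the measured study conditions: `n_subjects` subjects, each with
#' one rest and one meditation block of `n_timepoints` volumes at repetition
#' time `tr`, over `n_regions` regions. Signals are drawn from a zero-mean
#' multivariate Gaussian whose correlation matrix is block-structured: the
#' effect regions form one block, the remaining regions consecutive blocks of
#' `block_size`; within-block correlation is `rho0` everywhere except that in
#' the meditation condition the effect block's pairwise correlation is raised
#' to `rho1`. Between-block correlations are a small seeded jitter
#' (`N(0, jitter^2)`), and both implied correlation matrices are verified
#' positive semi-definite (non-PSD specs are rejected naming the offending
#' parameters). Each signal is then spectrally shaped by one common
#' frequency-domain filter that scales out-of-band amplitudes so the expected
#' in-band amplitude fraction equals `band_power_fraction`; a common filter
#' leaves the cross-region correlation structure intact.
#'
#' @param n_subjects Default 29.
#' @param n_regions Default 116.
#' @param n_timepoints Volumes per block; default 120 (a 5-min block at
#'   TR = 2.5 s).
#' @param tr Repetition time in seconds; default 2.5.
#' @param rho0 Baseline within-block correlation in `[0, 1)`; default 0.1.
#' @param rho1 Elevated effect-block correlation in `[rho0, 1)` for the
#'   meditation condition; default 0.9 (a strong planted effect).
#' @param effect_regions Region indices forming the effect block; default `1:8`.
#' @param band Band edges in Hz; default `c(0.008, 0.09)`.
#' @param band_power_fraction Target in-band fraction of spectral amplitude,
#'   in `(0, 1]`; default 0.8 (band-limited, as after band-pass
#'   preprocessing, with some residual broadband noise).
#' @param block_size Size of the baseline correlation blocks; default 8.
#' @param jitter SD of between-block correlations; default 0.002.
#' @param seed Integer seed.
#' @return A `timeseries_sim_spec` list.
#' @export
timeseries_sim_spec <- function(n_subjects = 29L, n_regions = 116L,
                                n_timepoints = 120L, tr = 2.5,
                                rho0 = 0.1, rho1 = 0.9,
                                effect_regions = 1:8,
                                band = c(0.008, 0.09),
                                band_power_fraction = 0.8,
                                block_size = 8L, jitter = 0.002,
                                seed = 1L) {
  if (n_timepoints < 8L) abort("`n_timepoints` must be >= 8.")
  if (!(rho0 >= 0 && rho0 < 1)) abort("`rho0` must lie in [0, 1).")
  if (!(rho1 >= rho0 && rho1 < 1)) abort("`rho1` must lie in [rho0, 1).")
  effect_regions <- sort(unique(as.integer(effect_regions)))
  if (length(effect_regions) == 0L ||
      any(effect_regions < 1L | effect_regions > n_regions)) {
    abort("`effect_regions` must be a nonempty subset of 1..n_regions.")
  }
  if (!(band_power_fraction > 0 && band_power_fraction <= 1)) {
    abort("`band_power_fraction` must lie in (0, 1].")
  }
  nyq <- 1 / (2 * tr)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] <= nyq + 1e-12)) {
    abort("`band` must satisfy 0 < low < high <= Nyquist.")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 rho0 = rho0, rho1 = rho1, effect_regions = effect_regions,
                 band = band, band_power_fraction = band_power_fraction,
                 block_size = as.integer(block_size), jitter = jitter,
                 seed = as.integer(seed)),
            class = "timeseries_sim_spec")
}

# Region partition: effect block first, remaining regions in consecutive
# blocks of block_size.
ts_sim_blocks <- function(spec) {
  rest <- setdiff(seq_len(spec$n_regions), spec$effect_regions)
  blocks <- list(spec$effect_regions)
  while (length(rest) > 0) {
    take <- head(rest, spec$block_size)
    blocks <- c(blocks, list(take))
    rest <- setdiff(rest, take)
  }
  blocks
}

ts_sim_sigma <- function(spec, condition) {
  j <- spec$n_regions
  blocks <- ts_sim_blocks(spec)
  sig <- matrix(0, j, j)
  if (spec$jitter > 0) {
    jit <- withr::with_seed(spec$seed + 999L, {
      z <- matrix(rnorm(j * j, sd = spec$jitter), j, j)
      (z + t(z)) / 2
    })
    sig <- jit
  }
  for (b in blocks) sig[b, b] <- spec$rho0
  if (condition == "meditation") {
    sig[spec$effect_regions, spec$effect_regions] <- spec$rho1
  }
  diag(sig) <- 1
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(paste0(
      "Implied %s-condition correlation matrix is not positive ",
      "semi-definite (min eigenvalue %.3g); adjust rho0 = %g, rho1 = %g ",
      "or jitter = %g."), condition, min(ev), spec$rho0, spec$rho1,
      spec$jitter))
  }
  sig
}

# Common spectral filter: scale amplitudes outside the band by alpha so the
# expected in-band amplitude fraction over a flat spectrum equals the target.
ts_sim_shape_spectrum <- function(x, tr, band, target) {
  tt <- nrow(x)
  freq <- dft_freqs(tt, tr)
  pos <- seq_len(floor(tt / 2)) + 1L # positive-frequency bins, DC excluded
  in_band_pos <- abs(freq[pos]) >= band[1] - 1e-12 &
    abs(freq[pos]) <= band[2] + 1e-12
  n_in <- sum(in_band_pos)
  n_out <- sum(!in_band_pos)
  alpha <- if (n_out == 0 || target >= 1) 0 else
    n_in * (1 - target) / (target * n_out)
  scale <- rep(alpha, tt)
  keep <- abs(freq) >= band[1] - 1e-12 & abs(freq) <= band[2] + 1e-12
  scale[keep] <- 1
  scale[1L] <- 0 # drop DC; means are irrelevant downstream
  xf <- stats::mvfft(x) * scale
  Re(stats::mvfft(xf, inverse = TRUE)) / tt
}

#' Simulate a two-condition ROI time-series dataset
#'
#' Draws, for every subject, one rest and one meditation block according to a
#' [timeseries_sim_spec()]. Fully seeded: identical specs give bitwise
#' identical datasets.
#'
#' @param spec A [timeseries_sim_spec()].
#' @return A list with `blocks` (a tibble with columns `subject_id`,
#'   `condition` and list-column `ts` of [roi_timeseries()]) and `truth`
#'   (effect regions, correlation parameters, block partition).
#' @export
simulate_timeseries_dataset <- function(spec) {
  stopifnot(inherits(spec, "timeseries_sim_spec"))
  sig_rest <- ts_sim_sigma(spec, "rest")
  sig_med <- ts_sim_sigma(spec, "meditation")
  chol_rest <- chol(sig_rest + diag(1e-10, spec$n_regions))
  chol_med <- chol(sig_med + diag(1e-10, spec$n_regions))
  region_names <- default_region_names(spec$n_regions)

  blocks <- withr::with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$n_subjects), function(s) {
      purrr::map_dfr(c("rest", "meditation"), function(cond) {
        ch <- if (cond == "rest") chol_rest else chol_med
        z <- matrix(rnorm(spec$n_timepoints * spec$n_regions),
                    spec$n_timepoints, spec$n_regions) %*% ch
        z <- ts_sim_shape_spectrum(z, spec$tr, spec$band,
                                   spec$band_power_fraction)
        ts <- roi_timeseries(z, subject_id = sprintf("S%03d", s),
                             condition = cond, tr = spec$tr,
                             region_names = region_names)
        tibble::tibble(subject_id = ts$subject_id,
                       condition = factor(cond, levels = c("rest", "meditation")),
                       ts = list(ts))
      })
    })
  })
  truth <- list(effect_regions = region_names[spec$effect_regions],
                effect_region_idx = spec$effect_regions,
                rho0 = spec$rho0, rho1 = spec$rho1,
                band = spec$band,
                band_power_fraction = spec$band_power_fraction,
                block_partition = ts_sim_blocks(spec),
                seed = spec$seed)
  list(blocks = blocks, truth = truth)
}
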