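#' ROI time-series block
#'
#' One subject-condition block of region-of-interest BOLD-like signals:
#' a numeric matrix with `T` time points (rows) and `J` regions (columns),
#' together with the sampling interval.
#'
#' @param data Numeric matrix, time points by regions. At least 8 rows, no
#'   missing values.
#' @param subject_id Character scalar.
#' @param condition One of `"rest"` or `"meditation"`.
#' @param tr Sampling interval in seconds (repetition time).
#' @param region_names Optional character vector of unique region names;
#'   defaults to the column names of `data` or `R001..RJJJ`.
#'
#' @return An object of class `roi_timeseries` with fields `data`,
#'   `subject_id`, `condition`, `tr`, `region_names`.
#' @export
roi_timeseries <- function(data, subject_id, condition = c("rest", "meditation"),
                           tr, region_names = NULL) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (nrow(data) < 8L) abort("`data` must have at least 8 time points.")
  if (anyNA(data)) abort("`data` must not contain missing values.")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    abort("`tr` must be a positive scalar (seconds).")
  }
  if (is.null(region_names)) {
    region_names <- colnames(data) %||% default_region_names(ncol(data))
  }
  if (length(region_names) != ncol(data)) {
    abort("`region_names` must have one entry per column of `data`.")
  }
  if (anyDuplicated(region_names)) abort("`region_names` must be unique.")
  colnames(data) <- region_names
  structure(
    list(data = data, subject_id = as.character(subject_id),
         condition = condition, tr = as.numeric(tr),
         region_names = as.character(region_names)),
    class = "roi_timeseries"
  )
}

default_region_names <- function(n) sprintf("R%03d", seq_len(n))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s, condition %s: %d time points x %d regions, TR = %gs\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Band-pass filter a time-series block
#'
#' Removes the linear trend and mean from each region's signal, then zeroes
#' every discrete Fourier component whose frequency falls outside
#' \[`low`, `high`\] (endpoints inclusive on the grid `k / (T * TR)`).
#' Exposed as a utility; the pipeline does not filter by default because the
#' synthetic generator already produces band-limited signals.
#'
#' @param ts A [roi_timeseries()].
#' @param low,high Band edges in Hz; `0 <= low < high <= 1/(2*TR)` (Nyquist).
#' @return A filtered [roi_timeseries()].
#' @export
ts_bandpass <- function(ts, low = 0.008, high = 0.09) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$tr)
  if (!(low >= 0 && low < high)) abort("Need 0 <= low < high.")
  if (high > nyquist + 1e-12) {
    abort(sprintf("`high` (%g Hz) exceeds the Nyquist frequency %g Hz.", high, nyquist))
  }
  x <- detrend_linear(ts$data)
  tt <- nrow(x)
  freq <- dft_freqs(tt, ts$tr)
  keep <- abs(freq) >= low - 1e-12 & abs(freq) <= high + 1e-12
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / tt
  out <- sweep(out, 2L, colMeans(out))
  ts$data <- out
  colnames(ts$data) <- ts$region_names
  ts
}

# Signed DFT frequency for each of the T bins (Hz).
dft_freqs <- function(t_len, tr) {
  k <- seq_len(t_len) - 1L
  k[k > t_len / 2] <- k[k > t_len / 2] - t_len
  k / (t_len * tr)
}

# Remove per-column mean and least-squares linear trend.
detrend_linear <- function(x) {
  tt <- nrow(x)
  tc <- seq_len(tt) - (tt + 1) / 2
  x <- sweep(x, 2L, colMeans(x))
  slope <- drop(crossprod(tc, x)) / sum(tc^2)
  x - outer(tc, slope)
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson correlations between every pair of region time courses, mapped to
#' Fisher z units (`atanh`), with r clamped to +/- (1 - 1e-7) beforehand so
#' duplicated signals stay finite. The diagonal is excluded (stored as `NA`)
#' and never enters thresholding or metrics.
#'
#' @param ts A [roi_timeseries()]. Every region must have nonzero variance.
#' @return An object of class `connectivity_matrix` with fields `z`
#'   (symmetric J x J matrix, `NA` diagonal) and `region_names`.
#' @export
connectivity_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance region(s): %s.",
                  paste(ts$region_names[sds == 0], collapse = ", ")))
  }
  r <- cor(ts$data)
  clamp <- 1 - 1e-7
  r[r > clamp] <- clamp
  r[r < -clamp] <- -clamp
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(list(z = z, region_names = ts$region_names),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d Fisher-z matrix\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Binarize a connectivity matrix by cost
#'
#' Retains the `m = round(cost * J*(J-1)/2)` strongest off-diagonal pairs
#' (rounding half away from zero). Ties at the cutoff are broken by ascending
#' lexicographic `(i, j)` order, so the output is deterministic and edge sets
#' are nested across costs.
#'
#' @param cm A [connectivity_matrix()].
#' @param cost Fraction of possible connections to keep, in `(0, 1]`. At
#'   `J = 116` and cost 0.100 this keeps 667 of the 6,670 possible edges.
#' @return An object of class `binary_network` with fields `adjacency`
#'   (0/1 symmetric, zero diagonal), `cost`, `edge_count`, `region_names`.
#' @export
binarize_by_cost <- function(cm, cost) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1) {
    abort("`cost` must be a scalar in (0, 1].")
  }
  j <- nrow(cm$z)
  n_possible <- j * (j - 1) / 2
  m <- floor(cost * n_possible + 0.5) # round half away from zero
  ut <- which(upper.tri(cm$z), arr.ind = TRUE)
  zv <- cm$z[ut]
  # Total order: z descending, then (i, j) ascending.
  ord <- order(-zv, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(m)]
  adj <- matrix(0, j, j, dimnames = list(cm$region_names, cm$region_names))
  adj[ut[keep, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  structure(list(adjacency = adj, cost = cost, edge_count = m,
                 region_names = cm$region_names),
            class = "binary_network")
}

#' Construct a binary network directly from an adjacency matrix
#'
#' Mostly useful for tests and worked examples; [binarize_by_cost()] is the
#' pipeline route.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param cost Optional cost annotation.
#' @return A `binary_network`.
#' @export
binary_network <- function(adjacency, cost = NA_real_) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency))) abort("`adjacency` must be symmetric.")
  if (any(diag(adjacency) != 0)) abort("`adjacency` must have a zero diagonal.")
  if (!all(adjacency %in% c(0, 1))) abort("`adjacency` must be 0/1.")
  nm <- colnames(adjacency) %||% default_region_names(ncol(adjacency))
  dimnames(adjacency) <- list(nm, nm)
  structure(list(adjacency = adjacency, cost = cost,
                 edge_count = sum(adjacency) / 2, region_names = nm),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (cost %s)\n",
              nrow(x$adjacency), x$edge_count,
              ifelse(is.na(x$cost), "unset", format(x$cost))))
  invisible(x)
}
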