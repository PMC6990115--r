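#' Specification for a synthetic feature tensor with a planted effect
#'
#' Defines a direct draw from the Tucker3 model
#' `X = U Y (C (x) B)' + sigma E`: the class indicator `U` encodes each
#' subject's rest and meditation observations, the first region component
#' `B[, 1]` is supported (unit-normalized) on a designated region subset, the
#' metric component `C` is concentrated on one metric, and the two class
#' centroids are separated by `delta` along the first component. A smaller
#' class-shared second component (weight `delta / 4`, supported on the
#' complementary regions) makes the planted two-column region subspace
#' identifiable in the noiseless case; at `delta = 0` the tensor is pure
#' Gaussian noise, giving an exact null.
#'
#' @param n_subjects Number of subjects (default 29; observations
#'   `I = 2 * n_subjects`).
#' @param n_regions Number of regions `J` (default 116).
#' @param n_metrics Number of metrics `K` (default 4: degree, betweenness,
#'   clustering, falff).
#' @param planted_regions Indices in `1..n_regions` carrying the effect
#'   (default `1:8`). Must be a nonempty proper subset.
#' @param planted_metric Index in `1..n_metrics` of the effect-carrying
#'   metric (default 3, the clustering coefficient).
#' @param delta Class-centroid separation along the first component, >= 0.
#' @param sigma Noise standard deviation, >= 0.
#' @param seed Integer seed.
#' @return A `tensor_sim_spec` list.
#' @export
tensor_sim_spec <- function(n_subjects = 29L, n_regions = 116L, n_metrics = 4L,
                            planted_regions = 1:8, planted_metric = 3L,
                            delta = 1, sigma = 0.1, seed = 1L) {
  if (n_subjects < 1L || n_regions < 2L || n_metrics < 1L) {
    abort("Need n_subjects >= 1, n_regions >= 2, n_metrics >= 1.")
  }
  planted_regions <- sort(unique(as.integer(planted_regions)))
  if (length(planted_regions) == 0L ||
      any(planted_regions < 1L | planted_regions > n_regions)) {
    abort("`planted_regions` must be a nonempty subset of 1..n_regions.")
  }
  if (length(planted_regions) >= n_regions) {
    abort("`planted_regions` must be a proper subset of the regions.")
  }
  if (!planted_metric %in% seq_len(n_metrics)) {
    abort("`planted_metric` must lie in 1..n_metrics.")
  }
  if (delta < 0) abort("`delta` must be >= 0.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_metrics = as.integer(n_metrics),
                 planted_regions = planted_regions,
                 planted_metric = as.integer(planted_metric),
                 delta = delta, sigma = sigma, seed = as.integer(seed)),
            class = "tensor_sim_spec")
}

#' Simulate a feature tensor from the Tucker3 model
#'
#' @param spec A [tensor_sim_spec()].
#' @return A list with elements `tensor` (a [feature_tensor()], raw scale)
#'   and `truth` (planted `B`, `C`, core `Y`, labels and spec parameters).
#' @export
simulate_feature_tensor <- function(spec) {
  stopifnot(inherits(spec, "tensor_sim_spec"))
  n <- spec$n_subjects
  j <- spec$n_regions
  k <- spec$n_metrics
  i_obs <- 2L * n

  obs <- tibble::tibble(
    subject_id = rep(sprintf("S%03d", seq_len(n)), each = 2L),
    condition = factor(rep(c("rest", "meditation"), times = n),
                       levels = c("rest", "meditation"))
  )
  u <- build_indicator(obs$condition)

  b <- matrix(0, j, 2L)
  b[spec$planted_regions, 1L] <- 1 / sqrt(length(spec$planted_regions))
  comp <- setdiff(seq_len(j), spec$planted_regions)
  b[comp, 2L] <- 1 / sqrt(length(comp))
  cmat <- matrix(0, k, 1L)
  cmat[spec$planted_metric, 1L] <- 1

  # Core (G x QR, component index q fastest): rest at -delta/2, meditation at
  # +delta/2 on component 1; shared delta/4 baseline on component 2.
  ym <- rbind(rest = c(-spec$delta / 2, spec$delta / 4),
              meditation = c(spec$delta / 2, spec$delta / 4))
  kbc <- kronecker(cmat, b) # JK x 2, row index region-fastest
  signal <- u %*% ym %*% t(kbc)
  noise <- withr::with_seed(spec$seed, matrix(rnorm(i_obs * j * k), i_obs, j * k))
  xm <- signal + spec$sigma * noise

  region_names <- default_region_names(j)
  metric_names <- if (k == 4L) .metric_order else sprintf("metric%d", seq_len(k))
  tensor <- new_feature_tensor(array(xm, dim = c(i_obs, j, k)), obs,
                               region_names, metric_names,
                               standardized = FALSE)
  truth <- list(B = b, C = cmat, core = ym,
                labels = obs$condition,
                planted_regions = region_names[spec$planted_regions],
                planted_region_idx = spec$planted_regions,
                planted_metric = metric_names[spec$planted_metric],
                planted_metric_idx = spec$planted_metric,
                delta = spec$delta, sigma = spec$sigma, seed = spec$seed)
  list(tensor = tensor, truth = truth)
}
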