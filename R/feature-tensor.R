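#' Three-way feature tensor (observations x regions x metrics)
#'
#' The container for the supervised Tucker3 analysis: `I = 2 * n_subjects`
#' observation rows (each subject once per condition, subjects ascending and
#' rest before meditation), `J` regions, `K` metrics in the fixed serialized
#' order degree, betweenness, clustering, falff.
#'
#' `assemble_feature_tensor()` builds the tensor from a long feature table;
#' every `(subject, condition, region, metric)` cell must be present exactly
#' once. `standardize_tensor()` z-scores each `(region, metric)` column
#' across observations (zero-variance columns become all-zero with a
#' warning); metrics live on incommensurate scales (degree counts versus
#' `[0, 1]` coefficients), so standardization is on by default in the
#' pipeline. `matricize()` unfolds to the `I x (J*K)` matrix with column
#' index `(k - 1) * J + j` (region fastest), the layout under which
#' `X %*% (C (x) B)` is well-posed; `refold_tensor()` inverts it.
#'
#' @param features Long tibble with columns `subject_id`, `condition`,
#'   `region`, `metric`, `value`.
#' @return `assemble_feature_tensor()` and `standardize_tensor()` return a
#'   `feature_tensor`; `matricize()` a numeric matrix; `refold_tensor()` a
#'   `feature_tensor`.
#' @export
assemble_feature_tensor <- function(features) {
  need <- c("subject_id", "condition", "region", "metric", "value")
  if (!all(need %in% names(features))) {
    abort(paste("`features` must have columns", paste(need, collapse = ", ")))
  }
  subjects <- sort(unique(as.character(features$subject_id)))
  conds <- c("rest", "meditation")
  if (!all(as.character(features$condition) %in% conds)) {
    abort("`condition` must be 'rest' or 'meditation'.")
  }
  regions <- sort(unique(as.character(features$region)))
  mets <- unique(as.character(features$metric))
  metric_names <- c(intersect(.metric_order, mets),
                    sort(setdiff(mets, .metric_order)))

  obs <- tibble::tibble(
    subject_id = rep(subjects, each = 2L),
    condition = factor(rep(conds, times = length(subjects)), levels = conds)
  )
  i_obs <- nrow(obs)
  full <- tidyr::expand_grid(
    obs_row = seq_len(i_obs),
    region = regions, metric = metric_names
  )
  full$subject_id <- obs$subject_id[full$obs_row]
  full$condition <- as.character(obs$condition[full$obs_row])

  keyed <- dplyr::mutate(features,
                         subject_id = as.character(.data$subject_id),
                         condition = as.character(.data$condition),
                         region = as.character(.data$region),
                         metric = as.character(.data$metric))
  dup <- dplyr::count(keyed, .data$subject_id, .data$condition,
                      .data$region, .data$metric)
  if (any(dup$n > 1L)) {
    d <- dup[dup$n > 1L, ][1L, ]
    abort(sprintf("Duplicate cell: subject %s, %s, region %s, metric %s.",
                  d$subject_id, d$condition, d$region, d$metric))
  }
  joined <- dplyr::left_join(
    full, keyed, by = c("subject_id", "condition", "region", "metric"))
  if (anyNA(joined$value)) {
    miss <- joined[is.na(joined$value), ][1L, ]
    abort(sprintf("Missing cell: subject %s, %s, region %s, metric %s.",
                  miss$subject_id, miss$condition, miss$region, miss$metric))
  }
  # full is ordered obs_row, then region, then metric (metric fastest);
  # fill the array accordingly: [i, j, k] with i fastest wants obs fastest.
  joined <- dplyr::arrange(joined,
                           match(.data$metric, metric_names),
                           match(.data$region, regions), .data$obs_row)
  x <- array(joined$value,
             dim = c(i_obs, length(regions), length(metric_names)))
  new_feature_tensor(x, obs, regions, metric_names, standardized = FALSE)
}

new_feature_tensor <- function(x, observation_index, region_names,
                               metric_names, standardized = FALSE) {
  stopifnot(length(dim(x)) == 3L,
            dim(x)[1] == nrow(observation_index),
            dim(x)[2] == length(region_names),
            dim(x)[3] == length(metric_names))
  structure(list(x = x, observation_index = observation_index,
                 region_names = as.character(region_names),
                 metric_names = as.character(metric_names),
                 standardized = isTRUE(standardized)),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<feature_tensor> %d observations x %d regions x %d metrics%s\n",
              d[1], d[2], d[3], if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @rdname assemble_feature_tensor
#' @param tensor A `feature_tensor`.
#' @export
standardize_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (tensor$standardized) abort("Tensor is already standardized.")
  xm <- matricize(tensor)
  mu <- colMeans(xm)
  sdv <- apply(xm, 2L, sd)
  zero <- sdv == 0
  if (any(zero)) {
    warn(sprintf("%d zero-variance (region, metric) column(s) set to zero.",
                 sum(zero)))
    sdv[zero] <- 1
  }
  xm <- sweep(sweep(xm, 2L, mu), 2L, sdv, "/")
  xm[, zero] <- 0
  new_feature_tensor(array(xm, dim = dim(tensor$x)),
                     tensor$observation_index, tensor$region_names,
                     tensor$metric_names, standardized = TRUE)
}

#' @rdname assemble_feature_tensor
#' @export
matricize <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  d <- dim(tensor$x)
  xm <- tensor$x
  dim(xm) <- c(d[1], d[2] * d[3])
  colnames(xm) <- paste(rep(tensor$region_names, times = d[3]),
                        rep(tensor$metric_names, each = d[2]), sep = ":")
  xm
}

#' @rdname assemble_feature_tensor
#' @param xm An `I x (J*K)` matrix in the region-fastest layout.
#' @param template A `feature_tensor` supplying axis metadata.
#' @export
refold_tensor <- function(xm, template) {
  stopifnot(inherits(template, "feature_tensor"))
  d <- dim(template$x)
  stopifnot(nrow(xm) == d[1], ncol(xm) == d[2] * d[3])
  new_feature_tensor(array(as.numeric(xm), dim = d),
                     template$observation_index, template$region_names,
                     template$metric_names, template$standardized)
}

#' Long tidy view of a feature tensor
#'
#' @param x A `feature_tensor`.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `condition`, `region`,
#'   `metric`, `value`.
#' @method tidy feature_tensor
#' @export
tidy.feature_tensor <- function(x, ...) {
  d <- dim(x$x)
  tibble::tibble(
    subject_id = rep(x$observation_index$subject_id, times = d[2] * d[3]),
    condition = rep(x$observation_index$condition, times = d[2] * d[3]),
    region = rep(rep(x$region_names, each = d[1]), times = d[3]),
    metric = rep(x$metric_names, each = d[1] * d[2]),
    value = as.numeric(x$x)
  )
}
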