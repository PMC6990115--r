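#' Compute all regional features for a two-condition dataset
#'
#' For every subject-condition block: build the Fisher-z connectivity matrix,
#' binarize it at `cost`, compute the three nodal graph metrics (degree,
#' betweenness, clustering coefficient), and compute fALFF from the time
#' series. Returns the long feature table consumed by
#' [assemble_feature_tensor()].
#'
#' @param blocks A tibble with columns `subject_id`, `condition` and a
#'   list-column `ts` of [roi_timeseries()] (as produced by
#'   [simulate_timeseries_dataset()] or [read_timeseries_dataset()]).
#' @param cost Cost threshold for binarization.
#' @param band fALFF band in Hz.
#' @param bandpass If `TRUE`, band-pass filter each block with `band` before
#'   computing connectivity and fALFF. Off by default: preprocessing is
#'   assumed done upstream and the synthetic generator is already
#'   band-shaped.
#' @return A tibble with columns `subject_id`, `condition`, `cost`, `region`,
#'   `metric`, `value`.
#' @export
compute_features <- function(blocks, cost, band = c(0.008, 0.09),
                             bandpass = FALSE) {
  check_blocks(blocks)
  purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    ts <- blocks$ts[[i]]
    if (bandpass) ts <- ts_bandpass(ts, band[1], band[2])
    net <- binarize_by_cost(connectivity_matrix(ts), cost)
    gm <- node_metrics(net)
    fa <- compute_falff(ts, band)
    out <- dplyr::bind_rows(
      gm,
      tibble::tibble(region = names(fa), metric = "falff",
                     value = as.numeric(fa))
    )
    out$subject_id <- blocks$subject_id[[i]]
    out$condition <- as.character(blocks$condition[[i]])
    out$cost <- cost
    out[, c("subject_id", "condition", "cost", "region", "metric", "value")]
  })
}

check_blocks <- function(blocks) {
  need <- c("subject_id", "condition", "ts")
  if (!all(need %in% names(blocks))) {
    abort("`blocks` must have columns subject_id, condition, ts.")
  }
  if (!all(purrr::map_lgl(blocks$ts, inherits, "roi_timeseries"))) {
    abort("`blocks$ts` must be a list of roi_timeseries objects.")
  }
  invisible(blocks)
}

#' Connectivity matrices for every block of a dataset
#'
#' @inheritParams compute_features
#' @return `blocks` with an added list-column `cm` of
#'   [connectivity_matrix()] objects.
#' @export
compute_connectivity <- function(blocks, bandpass = FALSE,
                                 band = c(0.008, 0.09)) {
  check_blocks(blocks)
  blocks$cm <- purrr::map(blocks$ts, function(ts) {
    if (bandpass) ts <- ts_bandpass(ts, band[1], band[2])
    connectivity_matrix(ts)
  })
  blocks
}
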