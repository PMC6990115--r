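#' Write and read a two-condition time-series dataset as TSV
#'
#' Each block is written as a tab-separated file with a header row of region
#' names and one row per time point. A `manifest.tsv` maps each file to its
#' `(subject_id, condition, tr)`; the ground truth (when present) is written
#' as `ground_truth.json`.
#'
#' @param sim A list with `blocks` (and optionally `truth`) as returned by
#'   [simulate_timeseries_dataset()], or a bare blocks tibble.
#' @param dir Output directory (created if needed).
#' @return `write_timeseries_dataset()` returns the manifest path
#'   invisibly; `read_timeseries_dataset()` returns a blocks tibble.
#' @export
write_timeseries_dataset <- function(sim, dir) {
  blocks <- if (is.data.frame(sim)) sim else sim$blocks
  check_blocks(blocks)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    ts <- blocks$ts[[i]]
    files[i] <- sprintf("%s_%s.tsv", ts$subject_id, ts$condition)
    readr::write_tsv(tibble::as_tibble(as.data.frame(ts$data)),
                     file.path(dir, files[i]))
  }
  manifest <- tibble::tibble(
    file = files,
    subject_id = blocks$subject_id,
    condition = as.character(blocks$condition),
    tr = purrr::map_dbl(blocks$ts, "tr"))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  if (!is.data.frame(sim) && !is.null(sim$truth)) {
    jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file.path(dir, "manifest.tsv"))
}

#' @rdname write_timeseries_dataset
#' @param manifest Path to a `manifest.tsv` with columns `file`,
#'   `subject_id`, `condition`, `tr`.
#' @export
read_timeseries_dataset <- function(manifest) {
  man <- readr::read_tsv(manifest, show_col_types = FALSE)
  need <- c("file", "subject_id", "condition", "tr")
  if (!all(need %in% names(man))) {
    abort(paste("Manifest must have columns", paste(need, collapse = ", ")))
  }
  base <- dirname(manifest)
  tibble::tibble(
    subject_id = as.character(man$subject_id),
    condition = factor(man$condition, levels = c("rest", "meditation")),
    ts = purrr::map(seq_len(nrow(man)), function(i) {
      dat <- as.matrix(readr::read_tsv(file.path(base, man$file[i]),
                                       show_col_types = FALSE))
      roi_timeseries(dat, subject_id = man$subject_id[i],
                     condition = man$condition[i], tr = man$tr[i])
    }))
}

#' Serialize connectivity matrices and binary networks
#'
#' `write_connectivity_tsv()` writes the square Fisher-z (or adjacency)
#' matrix with a region-name header column; `write_edge_list_tsv()` writes
#' the upper-triangle edge list `(region_i, region_j, z)`.
#'
#' @param x A [connectivity_matrix()] or [binary_network()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_connectivity_tsv <- function(x, path) {
  m <- if (inherits(x, "connectivity_matrix")) x$z else x$adjacency
  df <- tibble::as_tibble(as.data.frame(m))
  df <- dplyr::bind_cols(tibble::tibble(region = x$region_names), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
write_edge_list_tsv <- function(x, path) {
  m <- if (inherits(x, "connectivity_matrix")) x$z else x$adjacency
  ut <- which(upper.tri(m), arr.ind = TRUE)
  df <- tibble::tibble(region_i = x$region_names[ut[, 1L]],
                       region_j = x$region_names[ut[, 2L]],
                       z = m[ut])
  if (inherits(x, "binary_network")) {
    names(df)[3L] <- "edge"
    df <- df[df$edge > 0, ]
  }
  readr::write_tsv(df, path)
  invisible(path)
}
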