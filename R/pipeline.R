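#' Pipeline configuration
#'
#' Collects every scientific parameter of the end-to-end analysis in one
#' validated object; no stage has hidden defaults. Supply either `simulate`
#' (a [timeseries_sim_spec()]) or `manifest` (path to a dataset manifest,
#' see [read_timeseries_dataset()]).
#'
#' @param simulate Optional [timeseries_sim_spec()].
#' @param manifest Optional manifest path; exactly one of `simulate` /
#'   `manifest` must be given.
#' @param costs Cost grid for threshold selection.
#' @param cost Fixed cost threshold; if `NULL` the three-criterion
#'   [select_cost()] procedure chooses one from `costs`.
#' @param gamma Resolution parameter for community detection.
#' @param band fALFF band (Hz).
#' @param bandpass Band-pass filter blocks before analysis (default off).
#' @param Q,R,tol,max_iter Tucker configuration.
#' @param standardize Z-score each (region, metric) column before the fit
#'   (default `TRUE`; the four metrics live on incommensurate scales).
#' @param n_perm,scheme,alpha Permutation-test settings.
#' @param n_realizations Random references per network for the small-world
#'   criterion.
#' @param seed Integer seed; mandatory (all stochastic stages derive their
#'   seeds from it).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, manifest = NULL,
                            costs = cost_grid(), cost = 0.225,
                            gamma = 1.0, band = c(0.008, 0.09),
                            bandpass = FALSE,
                            Q = 2L, R = 1L, tol = 1e-9, max_iter = 500L,
                            standardize = TRUE,
                            n_perm = 10000L,
                            scheme = c("within_subject", "free"),
                            alpha = 0.05, n_realizations = 20L,
                            seed = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(simulate) == is.null(manifest)) {
    abort("Supply exactly one of `simulate` or `manifest`.")
  }
  if (!is.null(simulate) && !inherits(simulate, "timeseries_sim_spec")) {
    abort("`simulate` must be a timeseries_sim_spec.")
  }
  if (!is.null(manifest) && !file.exists(manifest)) {
    abort(sprintf("Manifest not found: %s", manifest))
  }
  if (is.null(seed)) abort("`seed` is mandatory.")
  if (!is.null(cost) && (cost <= 0 || cost > 1)) {
    abort("`cost` must lie in (0, 1].")
  }
  structure(list(simulate = simulate, manifest = manifest, costs = costs,
                 cost = cost, gamma = gamma, band = band,
                 bandpass = isTRUE(bandpass),
                 Q = as.integer(Q), R = as.integer(R), tol = tol,
                 max_iter = as.integer(max_iter),
                 standardize = isTRUE(standardize),
                 n_perm = as.integer(n_perm), scheme = scheme,
                 alpha = alpha, n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are the arguments of [pipeline_config()]; `simulate` is a mapping of
#' [timeseries_sim_spec()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    raw$simulate <- do.call(timeseries_sim_spec, raw$simulate)
  }
  if (!is.null(raw$band)) raw$band <- as.numeric(raw$band)
  if (!is.null(raw$costs)) raw$costs <- as.numeric(raw$costs)
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full brain-state discrimination pipeline
#'
#' Simulate or ingest ROI time series, build connectivity matrices, fix or
#' select the cost threshold, compute graph metrics and fALFF, assemble and
#' (optionally) standardize the feature tensor, fit the supervised Tucker3
#' model, run the permutation test on first-component loadings, the paired
#' t-test baseline, and the condition test on component scores, and write
#' TSV/JSON reports into `out_dir`. Reruns with the same configuration and
#' seed produce identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all intermediate results (`blocks`,
#'   `cost`, `features`, `tensor`, `fit`, `perm`, `ttest`, `scores`,
#'   `score_test`, `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  blocks <- run_stage("data", {
    if (!is.null(config$simulate)) {
      sim <- simulate_timeseries_dataset(config$simulate)
      sim$blocks
    } else {
      read_timeseries_dataset(config$manifest)
    }
  })

  blocks <- run_stage("connectivity", {
    compute_connectivity(blocks, bandpass = config$bandpass,
                         band = config$band)
  })

  selection <- NULL
  cost <- config$cost
  if (is.null(cost)) {
    selection <- run_stage("cost", {
      select_cost(blocks, config$costs, config$gamma,
                  config$n_realizations, seed = config$seed + 1L)
    })
    cost <- selection$selected_cost
  }

  features <- run_stage("features", {
    compute_features(blocks, cost, band = config$band,
                     bandpass = config$bandpass)
  })

  tensor_raw <- run_stage("tensor", assemble_feature_tensor(features))
  tensor <- if (config$standardize) {
    run_stage("standardize", standardize_tensor(tensor_raw))
  } else {
    tensor_raw
  }

  fit <- run_stage("fit", {
    t3clus(tensor, Q = config$Q, R = config$R, tol = config$tol,
           max_iter = config$max_iter)
  })
  perm <- run_stage("permutation", {
    permutation_test(tensor, Q = config$Q, R = config$R,
                     n_perm = config$n_perm, scheme = config$scheme,
                     seed = config$seed + 2L, alpha = config$alpha,
                     tol = config$tol, max_iter = config$max_iter)
  })
  ttest <- run_stage("ttest", paired_feature_ttests(tensor_raw, config$alpha))
  scores <- run_stage("scores", component_scores(fit, "raw"))
  score_test <- run_stage("score_test", score_condition_test(scores))

  cfg_for_hash <- config
  cfg_for_hash$simulate <- unclass(config$simulate)
  summary <- list(
    package_version = as.character(utils::packageVersion("brainstates")),
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    cost = cost,
    cost_selected = is.null(config$cost),
    loss = fit$loss,
    prop_explained = 1 - fit$loss / fit$ss_x,
    n_iter = fit$n_iter,
    converged = fit$converged,
    significant_regions = perm$regions$region[perm$regions$significant],
    significant_metrics = perm$metrics$metric[perm$metrics$significant],
    n_ttest_significant = sum(ttest$significant),
    score_test_p = score_test$p_value
  )

  run_stage("report", {
    readr::write_tsv(features, file.path(out_dir, "features.tsv"))
    readr::write_tsv(tidy(fit, "regions"),
                     file.path(out_dir, "loadings_regions.tsv"))
    readr::write_tsv(tidy(fit, "metrics"),
                     file.path(out_dir, "loadings_metrics.tsv"))
    readr::write_tsv(perm$regions,
                     file.path(out_dir, "permutation_regions.tsv"))
    readr::write_tsv(perm$metrics,
                     file.path(out_dir, "permutation_metrics.tsv"))
    readr::write_tsv(ttest, file.path(out_dir, "ttest_baseline.tsv"))
    readr::write_tsv(scores, file.path(out_dir, "component_scores.tsv"))
    if (!is.null(selection)) {
      readr::write_tsv(selection$table,
                       file.path(out_dir, "cost_selection.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(blocks = blocks, cost = cost, selection = selection,
                 features = features, tensor = tensor,
                 tensor_raw = tensor_raw, fit = fit, perm = perm,
                 ttest = ttest, scores = scores, score_test = score_test,
                 summary = summary, out_dir = out_dir))
}
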