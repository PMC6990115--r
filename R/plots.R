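#' Plot component scores of a fitted T3Clus model
#'
#' Scatter of the raw per-observation component scores, coloured by
#' condition (first two components; a one-component fit is plotted against
#' observation rank).
#'
#' @param object A [t3clus()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot t3clus_fit
#' @export
autoplot.t3clus_fit <- function(object, ...) {
  scores <- component_scores(object, "raw")
  if ("comp2" %in% names(scores)) {
    ggplot2::ggplot(scores, ggplot2::aes(.data$comp1, .data$comp2,
                                         colour = .data$condition)) +
      ggplot2::geom_point(size = 2, alpha = 0.8) +
      ggplot2::labs(x = "Component 1 score", y = "Component 2 score",
                    colour = "Condition") +
      ggplot2::theme_minimal()
  } else {
    scores$rank <- rank(scores$comp1)
    ggplot2::ggplot(scores, ggplot2::aes(.data$rank, .data$comp1,
                                         colour = .data$condition)) +
      ggplot2::geom_point(size = 2, alpha = 0.8) +
      ggplot2::labs(x = "Observation rank", y = "Component 1 score",
                    colour = "Condition") +
      ggplot2::theme_minimal()
  }
}

#' Plot permutation-test results on first-component loadings
#'
#' Absolute first-component loadings per region (and per metric), with
#' significant elements highlighted.
#'
#' @param object A [permutation_test()] result.
#' @param which `"regions"` or `"metrics"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot t3clus_perm
#' @export
autoplot.t3clus_perm <- function(object, which = c("regions", "metrics"),
                                 ...) {
  which <- match.arg(which)
  tab <- object[[which]]
  tab$name <- tab[[if (which == "regions") "region" else "metric"]]
  tab$name <- factor(tab$name, levels = tab$name[order(tab$abs_loading)])
  ggplot2::ggplot(tab, ggplot2::aes(.data$name, .data$abs_loading,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|first-component loading|",
                  fill = sprintf("p < %g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot the cost-selection criteria across the grid
#'
#' Degree-distribution similarity and community-count stability per feasible
#' cost, with the selected cost marked.
#'
#' @param object A [select_cost()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cost_selection
#' @export
autoplot.cost_selection <- function(object, ...) {
  tab <- tidyr::pivot_longer(
    object$table[, c("cost", "similarity", "stability_sd")],
    -"cost", names_to = "criterion", values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(.data$cost, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_cost,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "Cost threshold", y = NULL) +
    ggplot2::theme_minimal()
}
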