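#' Permutation test on first-component T3Clus loadings
#'
#' Identifies regions and metrics whose first-component loadings are larger
#' in absolute value than expected when the condition labels carry no
#' information. For each permutation the labels are shuffled, the indicator
#' rebuilt, the supervised Tucker3 model refitted, and the absolute
#' first-component region and metric loadings recorded. The p-value for each
#' element is `(1 + #{perm : |loading*| >= |loading_obs|}) / (n_perm + 1)`
#' (the +1 correction avoids zero p-values and is mildly conservative).
#' Region and metric loadings are tested separately; elements with
#' `p < alpha` are flagged significant without multiple-testing correction,
#' the reporting convention for this procedure in the functional-network
#' literature (Benjamini-Hochberg adjusted q-values are returned alongside).
#'
#' For speed, permutation refits use the single-start (HOSVD) fit; the
#' observed loadings here are computed by the identical procedure, so the
#' observed-versus-permuted comparison stays exchangeable and the p-values
#' valid.
#'
#' Permutation schemes: `"within_subject"` (default) swaps each subject's two
#' condition labels independently with probability 1/2, respecting the
#' paired design; `"free"` relabels observations uniformly at random while
#' preserving class sizes.
#'
#' @param tensor A [feature_tensor()] with both conditions present.
#' @param Q,R,tol,max_iter Tucker configuration (defaults `Q = 2`, `R = 1`).
#' @param n_perm Number of permutations (default 10000).
#' @param scheme Permutation scheme, see above.
#' @param seed Integer seed; with a fixed seed results are bit-reproducible.
#' @param alpha Significance level for flagging (default 0.05).
#' @return An object of class `t3clus_perm` with tibbles `regions`
#'   (`region`, `loading`, `abs_loading`, `p_value`, `q_value`,
#'   `significant`) and `metrics` (likewise), plus `n_perm`, `scheme`,
#'   `seed`, `alpha`.
#' @export
permutation_test <- function(tensor, Q = 2L, R = 1L, n_perm = 10000L,
                             scheme = c("within_subject", "free"),
                             seed = 1L, alpha = 0.05,
                             tol = 1e-9, max_iter = 500L) {
  stopifnot(inherits(tensor, "feature_tensor"))
  scheme <- match.arg(scheme)
  if (n_perm < 1L) abort("`n_perm` must be >= 1.")
  d <- dim(tensor$x)
  j <- d[2]
  k <- d[3]
  obs_idx <- tensor$observation_index
  labels <- as.character(obs_idx$condition)
  classes <- levels(obs_idx$condition) %||% sort(unique(labels))
  cls <- match(labels, classes)
  xm <- matricize(tensor)
  i_obs <- nrow(xm)

  if (scheme == "within_subject") {
    subj <- as.character(obs_idx$subject_id)
    pair_rows <- split(seq_len(i_obs), subj)
    if (any(lengths(pair_rows) != 2L)) {
      abort("Within-subject permutation needs each subject once per condition.")
    }
    pair_rows <- do.call(rbind, pair_rows) # n_subjects x 2
  }

  fit_abs_loadings <- function(cl) {
    u <- matrix(0, i_obs, 2L)
    u[cbind(seq_len(i_obs), cl)] <- 1
    ng <- colSums(u)
    w <- crossprod(u, xm) / sqrt(ng)
    f <- t3_fit_w(w, j, k, Q, R, tol = tol, max_iter = max_iter,
                  inits = "hosvd")
    list(b = f$B[, 1L], c = f$C[, 1L])
  }

  obs_fit <- fit_abs_loadings(cls)
  obs_b <- abs(obs_fit$b)
  obs_c <- abs(obs_fit$c)

  counts_b <- numeric(j)
  counts_c <- numeric(k)
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      if (scheme == "within_subject") {
        cl_p <- cls
        flip <- rbinom(nrow(pair_rows), 1L, 0.5) == 1L
        rows <- pair_rows[flip, , drop = FALSE]
        cl_p[rows] <- 3L - cl_p[rows]
      } else {
        cl_p <- cls[sample.int(i_obs)]
      }
      f <- fit_abs_loadings(cl_p)
      counts_b <- counts_b + (abs(f$b) >= obs_b)
      counts_c <- counts_c + (abs(f$c) >= obs_c)
    }
  })
  p_b <- (1 + counts_b) / (n_perm + 1)
  p_c <- (1 + counts_c) / (n_perm + 1)

  regions <- tibble::tibble(
    region = tensor$region_names,
    loading = as.numeric(obs_fit$b),
    abs_loading = as.numeric(obs_b),
    p_value = p_b,
    q_value = p.adjust(p_b, "BH"),
    significant = p_b < alpha)
  metrics <- tibble::tibble(
    metric = tensor$metric_names,
    loading = as.numeric(obs_fit$c),
    abs_loading = as.numeric(obs_c),
    p_value = p_c,
    q_value = p.adjust(p_c, "BH"),
    significant = p_c < alpha)
  structure(list(regions = regions, metrics = metrics,
                 n_perm = as.integer(n_perm), scheme = scheme,
                 seed = as.integer(seed), alpha = alpha),
            class = "t3clus_perm")
}

#' @export
print.t3clus_perm <- function(x, ...) {
  cat(sprintf(
    "<t3clus_perm> %d permutations (%s scheme): %d/%d regions, %d/%d metrics significant at alpha = %g\n",
    x$n_perm, x$scheme, sum(x$regions$significant), nrow(x$regions),
    sum(x$metrics$significant), nrow(x$metrics), x$alpha))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `t3clus_perm` object.
#' @param which `"regions"` or `"metrics"`.
#' @param ... Unused.
#' @method tidy t3clus_perm
#' @export
tidy.t3clus_perm <- function(x, which = c("regions", "metrics"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Paired condition test on component scores
#'
#' Paired t-test, per component, of the raw component scores between the two
#' conditions (each subject contributes one rest and one meditation score).
#' If every paired difference is exactly zero the component is reported with
#' `statistic = 0, p_value = 1`; a zero-variance set of nonzero differences
#' is degenerate and raises an error.
#'
#' @param scores A raw-mode score table from [component_scores()].
#' @return A tibble with `component`, `estimate` (mean meditation - rest
#'   difference), `statistic`, `df`, `p_value`.
#' @export
score_condition_test <- function(scores) {
  comp_cols <- grep("^comp", names(scores), value = TRUE)
  if (length(comp_cols) == 0L) abort("`scores` has no component columns.")
  conds <- levels(scores$condition) %||% sort(unique(as.character(scores$condition)))
  wide <- dplyr::arrange(scores, .data$subject_id, .data$condition)
  a <- wide[as.character(wide$condition) == conds[1L], ]
  b <- wide[as.character(wide$condition) == conds[2L], ]
  if (!identical(a$subject_id, b$subject_id)) {
    abort("Each subject must appear exactly once per condition.")
  }
  purrr::map_dfr(seq_along(comp_cols), function(ci) {
    diff <- b[[comp_cols[ci]]] - a[[comp_cols[ci]]]
    # same degeneracy criterion as t.test: stderr below ~10 eps of the mean
    degenerate <- sd(diff) == 0 ||
      sd(diff) / sqrt(length(diff)) < 10 * .Machine$double.eps * abs(mean(diff))
    if (degenerate) {
      if (all(abs(diff) <= .Machine$double.eps * 4 * max(abs(b[[comp_cols[ci]]]), 1))) {
        return(tibble::tibble(component = ci, estimate = 0, statistic = 0,
                              df = length(diff) - 1L, p_value = 1))
      }
      abort(sprintf(
        "Component %d: paired differences have zero variance (constant %g).",
        ci, diff[1L]))
    }
    tt <- t.test(diff)
    tibble::tibble(component = ci,
                   estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
}

#' Paired t-test baseline over all (region, metric) features
#'
#' The conventional mass-univariate approach: a paired t-test between the two
#' conditions for every `(region, metric)` cell, with Benjamini-Hochberg
#' false-discovery-rate adjustment across all `J * K` tests. Cells whose
#' paired differences have zero variance get `p = 1` with a warning.
#'
#' @param tensor A [feature_tensor()] on the raw feature scale (the paired t
#'   statistic is invariant to per-column standardization, but raw values
#'   keep the `estimate` column interpretable).
#' @param alpha Significance level applied to the adjusted q-values.
#' @return A tibble with `region`, `metric`, `estimate`, `statistic`,
#'   `p_value`, `q_value`, `significant`.
#' @export
paired_feature_ttests <- function(tensor, alpha = 0.05) {
  stopifnot(inherits(tensor, "feature_tensor"))
  obs_idx <- tensor$observation_index
  conds <- levels(obs_idx$condition)
  xm <- matricize(tensor)
  rows_a <- which(as.character(obs_idx$condition) == conds[1L])
  rows_b <- which(as.character(obs_idx$condition) == conds[2L])
  ord_a <- rows_a[order(obs_idx$subject_id[rows_a])]
  ord_b <- rows_b[order(obs_idx$subject_id[rows_b])]
  d <- xm[ord_b, , drop = FALSE] - xm[ord_a, , drop = FALSE]

  res <- purrr::map_dfr(seq_len(ncol(d)), function(jc) {
    di <- d[, jc]
    if (sd(di) == 0) {
      return(tibble::tibble(estimate = mean(di), statistic = NA_real_,
                            p_value = 1))
    }
    tt <- t.test(di)
    tibble::tibble(estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  })
  n_zero <- sum(is.na(res$statistic))
  if (n_zero > 0) {
    warn(sprintf("%d zero-variance feature cell(s) assigned p = 1.", n_zero))
  }
  j <- length(tensor$region_names)
  k <- length(tensor$metric_names)
  out <- tibble::tibble(
    region = rep(tensor$region_names, times = k),
    metric = rep(tensor$metric_names, each = j))
  out <- dplyr::bind_cols(out, res)
  out$q_value <- p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < alpha
  out
}

#' Overlap of selected regions across the cost grid
#'
#' For each region, the fraction of cost settings at which it was flagged as
#' discriminating, plus sub-range fractions for the lower and higher halves
#' of the grid (default split: lower up to 0.225, higher from 0.250 — 8 and
#' 11 of the 19 default costs).
#'
#' @param selections A list, one element per cost, of character vectors of
#'   selected regions.
#' @param costs Numeric vector of the same length as `selections`.
#' @param regions Universe of regions; defaults to the union of selections.
#' @param split Boundary between the lower and higher cost sub-ranges
#'   (lower: `cost <= split`).
#' @return A tibble with `region`, `n_selected`, `ratio`, `lower_ratio`,
#'   `higher_ratio`.
#' @export
overlap_ratio <- function(selections, costs, regions = NULL, split = 0.225) {
  if (length(selections) != length(costs)) {
    abort("`selections` and `costs` must have the same length.")
  }
  regions <- regions %||% sort(unique(unlist(selections)))
  lower <- costs <= split + 1e-12
  count_in <- function(idx) {
    if (!any(idx)) return(rep(0L, length(regions)))
    tab <- table(factor(unlist(selections[idx]), levels = regions))
    as.integer(tab)
  }
  n_all <- count_in(rep(TRUE, length(costs)))
  n_lo <- count_in(lower)
  n_hi <- count_in(!lower)
  tibble::tibble(
    region = regions,
    n_selected = n_all,
    ratio = n_all / length(costs),
    lower_ratio = if (any(lower)) n_lo / sum(lower) else NA_real_,
    higher_ratio = if (any(!lower)) n_hi / sum(!lower) else NA_real_)
}
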