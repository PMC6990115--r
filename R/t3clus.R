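#' Class indicator matrix
#'
#' Binary row-stochastic matrix `U` (`I x G`) with `U[i, g] = 1` iff
#' observation `i` belongs to class `g`. In the supervised T3Clus variant the
#' classes are the known experimental conditions, so `U` is fixed and never
#' optimized.
#'
#' @param labels Factor or character vector of class labels.
#' @param classes Optional class order; defaults to factor levels (or sorted
#'   unique values). Every class must be nonempty.
#' @return A binary matrix with one column per class.
#' @export
build_indicator <- function(labels, classes = NULL) {
  if (is.factor(labels)) {
    classes <- classes %||% levels(labels)
    labels <- as.character(labels)
  } else {
    labels <- as.character(labels)
    classes <- classes %||% sort(unique(labels))
  }
  if (!all(labels %in% classes)) {
    abort(sprintf("Unknown label(s): %s.",
                  paste(setdiff(labels, classes), collapse = ", ")))
  }
  u <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  u[cbind(seq_along(labels), match(labels, classes))] <- 1
  if (any(colSums(u) == 0)) {
    abort(sprintf("Empty class(es): %s.",
                  paste(classes[colSums(u) == 0], collapse = ", ")))
  }
  u
}

# Top-q left singular vectors, padded with an orthonormal complement if the
# matrix has fewer columns than q.
top_left_vectors <- function(m, q) {
  s <- svd(m, nu = min(q, min(dim(m))), nv = 0)
  u <- s$u
  if (ncol(u) < q) {
    full <- qr.Q(qr(cbind(u, diag(nrow(m)))))
    u <- full[, seq_len(q), drop = FALSE]
  }
  u
}

# HOOI core on the weighted class-mean matrix W (G x JK, region-fastest
# columns). Returns orthonormal B (J x Q), C (K x R), the core array
# (G x Q x R), the core-norm trace and convergence info. `scale_ss` sets the
# scale for the relative loss-change criterion (the squared norm of the data
# the loss is evaluated on). `inits = "all"` (default) runs the alternating
# iteration from the HOSVD initialization plus each of the K deterministic
# basis initializations of C and keeps the best objective — alternating
# updates can stall in local optima on unstructured data and the extra
# seed-free starts remove that failure mode; `inits = "hosvd"` is the
# single-start fast path (used inside permutation loops, where only
# consistency between the observed and permuted fits matters).
t3_fit_w <- function(w, j, k, q, r, tol = 1e-9, max_iter = 500L,
                     scale_ss = NULL, inits = c("all", "hosvd")) {
  inits <- match.arg(inits)
  g <- nrow(w)
  wa <- array(w, dim = c(g, j, k))
  wm2 <- matrix(aperm(wa, c(2, 1, 3)), j, g * k)
  wm3 <- matrix(aperm(wa, c(3, 1, 2)), k, g * j)
  scale_ss <- scale_ss %||% sum(w^2)
  denom <- max(scale_ss, .Machine$double.eps)

  core_from <- function(b, cc) {
    pb <- array(crossprod(b, wm2), dim = c(q, g, k)) # [q, g, k]
    cm <- matrix(aperm(pb, c(3, 1, 2)), k, q * g)
    core <- array(crossprod(cc, cm), dim = c(r, q, g)) # [r, q, g]
    aperm(core, c(3, 2, 1)) # [g, q, r]
  }
  b_step <- function(cc) {
    p3 <- array(crossprod(cc, wm3), dim = c(r, g, j)) # [r, g, j]
    top_left_vectors(matrix(aperm(p3, c(3, 2, 1)), j, g * r), q)
  }
  c_step <- function(b) {
    p2 <- array(crossprod(b, wm2), dim = c(q, g, k)) # [q, g, k]
    top_left_vectors(matrix(aperm(p2, c(3, 2, 1)), k, g * q), r)
  }

  run_from <- function(cc) {
    b <- b_step(cc)
    corenorm2 <- sum(core_from(b, cc)^2)
    trace <- corenorm2
    converged <- FALSE
    n_iter <- 0L
    for (it in seq_len(max_iter)) {
      n_iter <- it
      cc <- c_step(b)
      b <- b_step(cc)
      new_norm <- sum(core_from(b, cc)^2)
      trace <- c(trace, new_norm)
      delta <- new_norm - corenorm2
      corenorm2 <- new_norm
      if (abs(delta) <= tol * denom) {
        converged <- TRUE
        break
      }
    }
    list(b = b, cc = cc, corenorm2 = corenorm2, trace = trace,
         n_iter = n_iter, converged = converged)
  }

  starts <- list(top_left_vectors(wm3, r))
  if (inits == "all") {
    for (kk in seq_len(k)) {
      e <- matrix(0, k, r)
      e[cbind(((kk - 1L + seq_len(r) - 1L) %% k) + 1L, seq_len(r))] <- 1
      starts <- c(starts, list(e))
    }
  }
  best <- NULL
  for (s in starts) {
    res <- run_from(s)
    if (is.null(best) || res$corenorm2 > best$corenorm2 + 1e-12) best <- res
  }
  b <- best$b
  cc <- best$cc
  corenorm2 <- best$corenorm2
  trace <- best$trace
  n_iter <- best$n_iter
  converged <- best$converged

  core <- core_from(b, cc)
  # Order B columns by decreasing explained norm.
  expl_q <- vapply(seq_len(q), function(qi) sum(core[, qi, ]^2), numeric(1))
  oq <- order(-expl_q, seq_len(q))
  b <- b[, oq, drop = FALSE]
  core <- core[, oq, , drop = FALSE]
  if (r > 1L) {
    expl_r <- vapply(seq_len(r), function(ri) sum(core[, , ri]^2), numeric(1))
    orr <- order(-expl_r, seq_len(r))
    cc <- cc[, orr, drop = FALSE]
    core <- core[, , orr, drop = FALSE]
  }
  # Sign convention: the maximum-magnitude element of each column positive.
  for (qi in seq_len(q)) {
    im <- which.max(abs(b[, qi]))
    if (b[im, qi] < 0) {
      b[, qi] <- -b[, qi]
      core[, qi, ] <- -core[, qi, ]
    }
  }
  for (ri in seq_len(r)) {
    im <- which.max(abs(cc[, ri]))
    if (cc[im, ri] < 0) {
      cc[, ri] <- -cc[, ri]
      core[, , ri] <- -core[, , ri]
    }
  }
  list(B = b, C = cc, core = core, corenorm2 = corenorm2,
       corenorm2_trace = trace, n_iter = n_iter, converged = converged)
}

#' Supervised Tucker3 clustering (T3Clus) with a fixed class indicator
#'
#' Fits the Tucker3 model `X = U Y (C (x) B)' + E` by minimizing
#' `||X - U Y (C (x) B)'||^2` over column-orthonormal loading matrices `B`
#' (`J x Q`, regions) and `C` (`K x R`, metrics) and the core centroid array
#' `Y` (`G x Q x R`), with the binary row-stochastic indicator `U` fixed to
#' the known condition labels. With `U` fixed the optimal core given
#' `(B, C)` is `(U'U)^{-1} U' X (C (x) B)`, and the problem reduces to an
#' orthogonal Tucker decomposition of the weighted class-mean tensor
#' `W = (U'U)^{-1/2} U' X`; this is solved by higher-order orthogonal
#' iteration (HOOI) run from the HOSVD initialization (leading singular
#' vectors of `W`'s mode unfoldings) plus one deterministic basis
#' initialization of `C` per metric, keeping the best objective —
#' alternating updates can stall in local optima on unstructured data, and
#' the seed-free extra starts remove that failure mode without introducing
#' randomness. The objective is non-increasing across iterations of each
#' run.
#'
#' Determinism conventions: columns of `B` are ordered by decreasing
#' explained norm and each column of `B` and `C` is sign-flipped so its
#' maximum-magnitude element is positive. With `Q = 2` the individual
#' columns are rotation-ambiguous within the fitted subspace; downstream
#' inference therefore uses absolute loadings.
#'
#' @param tensor A [feature_tensor()] (standardize first via
#'   [standardize_tensor()] when metrics live on different scales).
#' @param Q Number of region components (default 2).
#' @param R Number of metric components (default 1).
#' @param tol Relative loss-change convergence threshold (default 1e-9),
#'   measured against the squared norm of the data.
#' @param max_iter Maximum HOOI iterations (default 500).
#' @return An object of class `t3clus_fit` with elements `B`, `C`, `core`
#'   (`G x Q x R`), `Ym` (matricized full-problem centroids), `loss`,
#'   `loss_trace`, `n_iter`, `converged`, `U`, `classes`, plus axis metadata.
#' @export
t3clus <- function(tensor, Q = 2L, R = 1L, tol = 1e-9, max_iter = 500L) {
  stopifnot(inherits(tensor, "feature_tensor"))
  d <- dim(tensor$x)
  j <- d[2]
  k <- d[3]
  if (!(Q >= 1 && Q <= j)) abort("Need 1 <= Q <= J.")
  if (!(R >= 1 && R <= k)) abort("Need 1 <= R <= K.")
  labels <- tensor$observation_index$condition
  u <- build_indicator(labels)
  ng <- colSums(u)
  xm <- matricize(tensor)
  ss_x <- sum(xm^2)
  w <- crossprod(u, xm) / sqrt(ng)

  fit <- t3_fit_w(w, j, k, Q, R, tol = tol, max_iter = max_iter,
                  scale_ss = ss_x)
  if (!fit$converged) {
    warn(sprintf("HOOI did not converge in %d iterations.", max_iter))
  }
  dimnames(fit$B) <- list(tensor$region_names, paste0("comp", seq_len(Q)))
  dimnames(fit$C) <- list(tensor$metric_names, paste0("comp", seq_len(R)))

  core_m <- matrix(fit$core, nrow(w), Q * R) # G x QR, q fastest
  ym <- sweep(core_m, 1L, sqrt(ng), "/")     # (U'U)^{-1} U' X (C (x) B)
  kbc <- kronecker(fit$C, fit$B)
  loss <- sum((xm - u %*% ym %*% t(kbc))^2)

  structure(list(
    B = fit$B, C = fit$C, core = fit$core, Ym = ym,
    loss = loss, loss_trace = ss_x - fit$corenorm2_trace,
    n_iter = fit$n_iter, converged = fit$converged,
    config = list(G = ncol(u), Q = Q, R = R, tol = tol, max_iter = max_iter),
    U = u, classes = colnames(u),
    observation_index = tensor$observation_index,
    Xm = xm, ss_x = ss_x,
    region_names = tensor$region_names,
    metric_names = tensor$metric_names,
    standardized = tensor$standardized
  ), class = "t3clus_fit")
}

#' @export
print.t3clus_fit <- function(x, ...) {
  cat(sprintf(
    "<t3clus_fit> G = %d, Q = %d, R = %d; loss = %.6g (%.1f%% explained), %d iterations%s\n",
    x$config$G, x$config$Q, x$config$R, x$loss,
    100 * (1 - x$loss / x$ss_x), x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Component scores of a fitted T3Clus model
#'
#' `mode = "raw"` returns the per-observation scores `X (C (x) B)`;
#' `mode = "centroid"` projects them onto the class means,
#' `U (U'U)^{-1} U' X (C (x) B)`, which are constant within each class. Raw
#' scores are the default for plotting and for the condition test on scores,
#' since they retain per-participant variation.
#'
#' @param fit A [t3clus()] fit.
#' @param mode `"raw"` or `"centroid"`.
#' @return A tibble with `subject_id`, `condition` and one column per
#'   component (`comp1`, ..., `compQR`); attribute `mode` records the choice.
#' @export
component_scores <- function(fit, mode = c("raw", "centroid")) {
  stopifnot(inherits(fit, "t3clus_fit"))
  mode <- match.arg(mode)
  kbc <- kronecker(fit$C, fit$B)
  raw <- fit$Xm %*% kbc
  if (mode == "centroid") {
    ng <- colSums(fit$U)
    raw <- fit$U %*% sweep(crossprod(fit$U, raw), 1L, ng, "/")
  }
  colnames(raw) <- paste0("comp", seq_len(ncol(raw)))
  out <- dplyr::bind_cols(fit$observation_index, tibble::as_tibble(raw))
  attr(out, "mode") <- mode
  out
}

#' Loading tables of a fitted T3Clus model
#'
#' @param x A `t3clus_fit`.
#' @param matrix Which loadings: `"regions"` (columns of `B`), `"metrics"`
#'   (columns of `C`) or `"kronecker"` (the full `C (x) B` weight table, one
#'   row per region-metric pair and component pair).
#' @param ... Unused.
#' @return A tibble of loadings.
#' @method tidy t3clus_fit
#' @export
tidy.t3clus_fit <- function(x, matrix = c("regions", "metrics", "kronecker"),
                            ...) {
  matrix <- match.arg(matrix)
  q <- x$config$Q
  r <- x$config$R
  if (matrix == "regions") {
    return(tibble::tibble(
      region = rep(x$region_names, times = q),
      component = rep(seq_len(q), each = length(x$region_names)),
      loading = as.numeric(x$B)))
  }
  if (matrix == "metrics") {
    return(tibble::tibble(
      metric = rep(x$metric_names, times = r),
      component = rep(seq_len(r), each = length(x$metric_names)),
      loading = as.numeric(x$C)))
  }
  j <- length(x$region_names)
  k <- length(x$metric_names)
  tibble::tibble(
    region = rep(rep(x$region_names, times = k), times = q * r),
    metric = rep(rep(x$metric_names, each = j), times = q * r),
    component = rep(seq_len(q * r), each = j * k),
    loading = as.numeric(kronecker(x$C, x$B)))
}

#' One-row model summary
#'
#' @param x A `t3clus_fit`.
#' @param ... Unused.
#' @return A tibble with loss, proportion of squared norm explained,
#'   iteration count and convergence flag.
#' @method glance t3clus_fit
#' @export
glance.t3clus_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss,
                 prop_explained = 1 - x$loss / x$ss_x,
                 n_iter = x$n_iter, converged = x$converged,
                 G = x$config$G, Q = x$config$Q, R = x$config$R)
}
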