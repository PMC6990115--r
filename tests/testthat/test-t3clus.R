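test_that("indicator construction encodes labels and rejects bad input", {
  u <- build_indicator(c("rest", "meditation", "rest"),
                       classes = c("rest", "meditation"))
  expect_equal(unname(u), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(unname(crossprod(u)), diag(c(2, 1)))
  expect_error(build_indicator(c("rest", "unknown"),
                               classes = c("rest", "meditation")), "Unknown")
  expect_error(build_indicator(factor(c("a", "a"), levels = c("a", "b"))),
               "Empty class")
})

test_that("identical rows within class are represented exactly at Q=J, R=K", {
  n <- 3
  j <- 3
  k <- 2
  rowA <- withr::with_seed(1, rnorm(j * k))
  rowB <- withr::with_seed(2, rnorm(j * k))
  x <- rbind(matrix(rowA, n, j * k, byrow = TRUE),
             matrix(rowB, n, j * k, byrow = TRUE))[rep(1:(2 * n)), ]
  obs <- tibble::tibble(
    subject_id = rep(sprintf("S%03d", 1:n), times = 2),
    condition = factor(rep(c("rest", "meditation"), each = n),
                       levels = c("rest", "meditation")))
  ord <- order(obs$subject_id, obs$condition)
  tens <- brainstates:::new_feature_tensor(
    array(x[ord, ], c(2 * n, j, k)), obs[ord, ],
    sprintf("R%03d", 1:j), c("m1", "m2"))
  fit <- t3clus(tens, Q = j, R = k)
  expect_lt(fit$loss, 1e-20)
})

test_that("loss matches a dense optimizer oracle on small instances (Q=R=1)", {
  withr::with_seed(17, {
    for (rep in 1:6) {
      xm <- matrix(rnorm(8 * 6), 8, 6) # I=8, J=3, K=2
      labels <- factor(rep(c("rest", "meditation"), 4),
                       levels = c("rest", "meditation"))
      obs <- tibble::tibble(subject_id = rep(sprintf("S%03d", 1:4), each = 2),
                            condition = labels)
      tens <- brainstates:::new_feature_tensor(
        array(xm, c(8, 3, 2)), obs, sprintf("R%03d", 1:3), c("m1", "m2"))
      fit <- t3clus(tens, Q = 1, R = 1)
      oracle <- bf_t3_loss_q1r1(xm, fit$U, 3, 2)
      expect_equal(fit$loss, oracle, tolerance = 1e-6)
    }
  })
})

test_that("HOOI loss is non-increasing and bounded below by the within-class part", {
  sim <- simulate_feature_tensor(tensor_sim_spec(
    n_subjects = 10, n_regions = 25, planted_regions = 1:5,
    delta = 1, sigma = 0.8, seed = 3))
  fit <- t3clus(sim$tensor)
  expect_true(all(diff(fit$loss_trace) <= 1e-8))
  # irreducible within-class residual ||X - P_U X||^2
  xm <- matricize(sim$tensor)
  pux <- fit$U %*% (diag(1 / colSums(fit$U)) %*% crossprod(fit$U, xm))
  expect_gte(fit$loss, sum((xm - pux)^2) - 1e-8)
  # orthonormal loadings
  expect_equal(crossprod(fit$B), diag(2), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(crossprod(fit$C), diag(1), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("fit is invariant to observation order and class relabeling", {
  sim <- simulate_feature_tensor(tensor_sim_spec(
    n_subjects = 7, n_regions = 15, planted_regions = 1:4,
    delta = 1.5, sigma = 0.5, seed = 6))
  fit <- t3clus(sim$tensor)
  perm <- withr::with_seed(8, sample.int(14))
  tens_p <- brainstates:::new_feature_tensor(
    sim$tensor$x[perm, , ], sim$tensor$observation_index[perm, ],
    sim$tensor$region_names, sim$tensor$metric_names)
  fit_p <- t3clus(tens_p)
  expect_equal(fit_p$loss, fit$loss, tolerance = 1e-9)
  expect_equal(abs(fit_p$B), abs(fit$B), tolerance = 1e-7)

  # swapping the level order (relabeling classes) changes neither loss nor
  # absolute loadings
  tens_r <- sim$tensor
  tens_r$observation_index$condition <-
    factor(as.character(tens_r$observation_index$condition),
           levels = c("meditation", "rest"))
  fit_r <- t3clus(tens_r)
  expect_equal(fit_r$loss, fit$loss, tolerance = 1e-9)
  expect_equal(abs(fit_r$B), abs(fit$B), tolerance = 1e-7)
})

test_that("reduced-problem loss identity holds on full X", {
  sim <- simulate_feature_tensor(tensor_sim_spec(
    n_subjects = 6, n_regions = 12, planted_regions = 1:3,
    delta = 1, sigma = 0.7, seed = 11))
  fit <- t3clus(sim$tensor)
  xm <- matricize(sim$tensor)
  u <- fit$U
  w <- crossprod(u, xm) / sqrt(colSums(u))
  kbc <- kronecker(fit$C, fit$B)
  within_ss <- sum(xm^2) - sum(w^2)
  loss_w <- sum(w^2) - sum((w %*% kbc)^2)
  expect_equal(fit$loss, within_ss + loss_w, tolerance = 1e-8)
})

test_that("component scores satisfy the projection identities", {
  sim <- simulate_feature_tensor(tensor_sim_spec(
    n_subjects = 8, n_regions = 14, planted_regions = 1:4,
    delta = 2, sigma = 0.5, seed = 13))
  fit <- t3clus(sim$tensor)
  raw <- component_scores(fit, "raw")
  cen <- component_scores(fit, "centroid")
  # centroid scores constant within class
  for (cond in c("rest", "meditation")) {
    sub <- cen[as.character(cen$condition) == cond, c("comp1", "comp2")]
    expect_equal(apply(sub, 2, sd), c(comp1 = 0, comp2 = 0), tolerance = 1e-10)
  }
  # class means of raw scores equal centroid scores
  for (cond in c("rest", "meditation")) {
    m_raw <- colMeans(raw[as.character(raw$condition) == cond,
                          c("comp1", "comp2")])
    m_cen <- colMeans(cen[as.character(cen$condition) == cond,
                          c("comp1", "comp2")])
    expect_equal(m_raw, m_cen, tolerance = 1e-10)
  }
  # orthonormal projection contracts the norm
  expect_lte(sum(as.matrix(raw[, c("comp1", "comp2")])^2),
             sum(matricize(sim$tensor)^2) + 1e-10)
})

test_that("loading tables match the Kronecker structure elementwise", {
  sim <- simulate_feature_tensor(tensor_sim_spec(
    n_subjects = 5, n_regions = 9, planted_regions = 1:3,
    delta = 1, sigma = 0.3, seed = 19))
  fit <- t3clus(sim$tensor)
  kron <- tidy(fit, "kronecker")
  j <- length(fit$region_names)
  for (row in c(1, 5, 17, nrow(kron))) {
    rr <- kron[row, ]
    jj <- match(rr$region, fit$region_names)
    kk <- match(rr$metric, fit$metric_names)
    qq <- (rr$component - 1) %% fit$config$Q + 1
    rr_comp <- (rr$component - 1) %/% fit$config$Q + 1
    expect_equal(rr$loading, fit$C[kk, rr_comp] * fit$B[jj, qq])
  }
  expect_equal(sqrt(colSums(fit$B^2)), c(comp1 = 1, comp2 = 1),
               tolerance = 1e-10)
  expect_equal(nrow(tidy(fit, "regions")), 2 * j)
})
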