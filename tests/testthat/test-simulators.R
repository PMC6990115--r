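test_that("tensor simulator is seeded-deterministic with exact class centroids", {
  spec <- tensor_sim_spec(n_subjects = 5, n_regions = 12,
                          planted_regions = 2:4, delta = 1.5,
                          sigma = 0.2, seed = 9)
  a <- simulate_feature_tensor(spec)
  b <- simulate_feature_tensor(spec)
  expect_identical(a$tensor$x, b$tensor$x)
  expect_equal(dim(a$tensor$x), c(10, 12, 4))

  # noise-free class column means equal the centroid rows exactly
  spec0 <- tensor_sim_spec(n_subjects = 5, n_regions = 12,
                           planted_regions = 2:4, delta = 1.5, sigma = 0,
                           seed = 9)
  s0 <- simulate_feature_tensor(spec0)
  xm <- matricize(s0$tensor)
  med <- as.character(s0$tensor$observation_index$condition) == "meditation"
  kbc <- kronecker(s0$truth$C, s0$truth$B)
  expect_equal(colMeans(xm[med, ]),
               drop(kbc %*% s0$truth$core["meditation", ]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(colMeans(xm[!med, ]),
               drop(kbc %*% s0$truth$core["rest", ]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("tensor spec validates its parameters", {
  expect_error(tensor_sim_spec(delta = -1), "delta")
  expect_error(tensor_sim_spec(sigma = -0.1), "sigma")
  expect_error(tensor_sim_spec(planted_regions = integer(0)), "planted_regions")
  expect_error(tensor_sim_spec(n_regions = 5, planted_regions = 1:5), "proper")
  expect_error(tensor_sim_spec(planted_metric = 9), "planted_metric")
})

test_that("noiseless planted tensors are recovered exactly by the fit", {
  sim <- simulate_feature_tensor(tensor_sim_spec(
    n_subjects = 6, n_regions = 20, planted_regions = 3:6,
    delta = 1, sigma = 0, seed = 4))
  fit <- t3clus(sim$tensor)
  expect_lte(fit$loss, 1e-10)
  top <- order(-abs(fit$B[, 1]))[1:4]
  expect_setequal(top, 3:6)
  expect_equal(max(abs(fit$C[, 1])), 1, tolerance = 1e-8)
})

test_that("time-series simulator honours its dimension and seeding contracts", {
  spec <- timeseries_sim_spec(n_subjects = 3, n_regions = 10,
                              n_timepoints = 40, effect_regions = 1:3,
                              block_size = 3, seed = 5)
  sim <- simulate_timeseries_dataset(spec)
  expect_equal(nrow(sim$blocks), 6)
  expect_equal(table(as.character(sim$blocks$condition)),
               table(rep(c("meditation", "rest"), 3)))
  expect_true(all(purrr::map_lgl(sim$blocks$ts,
                                 ~ all(dim(.x$data) == c(40, 10)))))
  sim2 <- simulate_timeseries_dataset(spec)
  expect_identical(purrr::map(sim$blocks$ts, "data"),
                   purrr::map(sim2$blocks$ts, "data"))
})

test_that("effect-pair correlations converge to rho1 and non-PSD specs fail", {
  spec <- timeseries_sim_spec(n_subjects = 1, n_regions = 9,
                              n_timepoints = 10000, rho0 = 0.2, rho1 = 0.7,
                              effect_regions = 1:3, block_size = 3,
                              band_power_fraction = 1, jitter = 0, seed = 8)
  sim <- simulate_timeseries_dataset(spec)
  med <- sim$blocks$ts[[which(sim$blocks$condition == "meditation")]]
  r_eff <- cor(med$data[, 1:3])
  expect_lt(max(abs(r_eff[upper.tri(r_eff)] - 0.7)), 0.05)
  rest <- sim$blocks$ts[[which(sim$blocks$condition == "rest")]]
  r0 <- cor(rest$data[, 1:3])
  expect_lt(max(abs(r0[upper.tri(r0)] - 0.2)), 0.05)

  bad <- timeseries_sim_spec(n_subjects = 1, n_regions = 12, rho0 = 0.1,
                             rho1 = 0.95, effect_regions = 1:8,
                             jitter = 0.2, seed = 1)
  expect_error(simulate_timeseries_dataset(bad), "positive semi-definite")
})

test_that("spectral shaping hits the target in-band amplitude fraction", {
  spec <- timeseries_sim_spec(n_subjects = 2, n_regions = 6,
                              effect_regions = 1:2, block_size = 2,
                              band_power_fraction = 0.8, seed = 3)
  sim <- simulate_timeseries_dataset(spec)
  fa <- purrr::map_dbl(sim$blocks$ts, ~ mean(compute_falff(.x)))
  expect_equal(mean(fa), 0.8, tolerance = 0.03)
})

test_that("planted effect raises the effect regions' clustering coefficient", {
  sim <- tiny_dataset(n_subjects = 6, j = 16, t_len = 80, rho1 = 0.9,
                      effect = 1:4, seed = 12)
  feats <- compute_features(sim$blocks, cost = 0.225)
  cc <- dplyr::filter(feats, metric == "clustering",
                      region %in% sim$truth$effect_regions)
  means <- tapply(cc$value, as.character(cc$condition), mean)
  expect_gt(means[["meditation"]], means[["rest"]])
})
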