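# Small in-code fixtures shared across test files.

toy_ts <- function(t_len = 64, j = 5, tr = 2.5, seed = 42,
                   subject = "S001", condition = "rest") {
  withr::with_seed(seed, {
    roi_timeseries(matrix(rnorm(t_len * j), t_len, j),
                   subject_id = subject, condition = condition, tr = tr)
  })
}

sinusoid_ts <- function(freqs, t_len = 120, tr = 2.5, noise = 0) {
  tt <- (seq_len(t_len) - 1) * tr
  dat <- vapply(freqs, function(f) cos(2 * pi * f * tt), numeric(t_len))
  if (noise > 0) dat <- dat + matrix(rnorm(t_len * length(freqs), sd = noise),
                                     t_len, length(freqs))
  roi_timeseries(dat, subject_id = "S001", condition = "rest", tr = tr)
}

# Tiny two-condition dataset: n subjects, j regions, fast to analyze.
tiny_dataset <- function(n_subjects = 4, j = 16, t_len = 60, rho1 = 0.85,
                         effect = 1:4, seed = 7, block_size = 4) {
  simulate_timeseries_dataset(timeseries_sim_spec(
    n_subjects = n_subjects, n_regions = j, n_timepoints = t_len,
    rho0 = 0.1, rho1 = rho1, effect_regions = effect,
    block_size = block_size, seed = seed))
}

# Connectivity matrix with prescribed z values (symmetric, NA diagonal).
cm_from_z <- function(z) {
  diag(z) <- NA_real_
  nm <- sprintf("R%03d", seq_len(nrow(z)))
  structure(list(z = z, region_names = nm), class = "connectivity_matrix")
}
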