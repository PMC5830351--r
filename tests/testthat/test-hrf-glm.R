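test_that("canonical HRF matches the stated double-gamma form", {
  # independent evaluation of the double-gamma difference, peak-normalised
  oracle <- function(t) {
    h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
    tt <- seq(0, 32, by = 0.001)
    hh <- dgamma(tt, shape = 6, rate = 1) - dgamma(tt, shape = 16, rate = 1) / 6
    h / max(hh)
  }
  t <- seq(0, 32, by = 0.1)
  expect_equal(canonical_hrf(t), oracle(t), tolerance = 1e-8)
  expect_equal(canonical_hrf(0), 0)
  expect_equal(t[which.max(canonical_hrf(t))], 5.0, tolerance = 0.101)
  expect_equal(max(canonical_hrf(t)), 1, tolerance = 1e-6)
  expect_equal(canonical_hrf(c(0, 33, 40)), c(0, 0, 0))
  expect_error(canonical_hrf(c(1, 0.5)), "increasing")
  expect_error(canonical_hrf(-1), "non-negative")
})

test_that("design matrix has one column per stimulus plus confounds", {
  d <- generate_design(seed = 21)
  n_scans <- ceiling((attr(d, "total_duration_s") + 20) / 1.98)
  nuis <- matrix(rnorm(n_scans * 6), n_scans, 6)
  dm <- build_design_matrix(d, 1.98, n_scans, nuisance = nuis,
                            include_us_regressors = TRUE)
  expect_equal(ncol(dm$X), 120 + 18 + 6 + 1)
  expect_equal(length(dm$trial_cols), 120)
  expect_equal(length(dm$us_cols), 18)
  # every trial regressor carries mass (HRF positive near its peak)
  expect_true(all(colSums(dm$X[, dm$trial_cols]) > 0))

  dm0 <- build_design_matrix(d, 1.98, n_scans, include_us_regressors = FALSE)
  expect_equal(ncol(dm0$X), 120 + 1)
})

test_that("near-coincident onsets and rank deficiency are reported", {
  d <- generate_design(n_trials = 6, pairing_rate = 0, n_initial_paired = 0,
                       seed = 2)
  d2 <- d
  d2$onset[2] <- d2$onset[1] + 0.3  # closer than tr/2
  expect_warning(build_design_matrix(d2, 1.98, 60), "collinear")
  d3 <- d
  d3$onset[2] <- d3$onset[1]  # duplicated regressor
  expect_error(suppressWarnings(build_design_matrix(d3, 1.98, 60)),
               "rank deficient")
})

test_that("discrete-cosine filter removes slow and keeps fast components", {
  tr <- 1.98
  n <- 340  # ~673-s record
  t <- (seq_len(n) - 1) * tr
  slow <- cos(2 * pi * t / 256)
  fast <- cos(2 * pi * t / 20)
  out_slow <- high_pass(rbind(slow), tr, 128)
  out_fast <- high_pass(rbind(fast), tr, 128)
  expect_lt(sd(out_slow) / sd(slow), 0.05)
  expect_gt(sd(out_fast) / sd(fast), 0.95)
  # constant series untouched; per-voxel mean preserved
  const <- rbind(rep(7, n))
  expect_equal(high_pass(const, tr, 128), const)
  mixed <- rbind(5 + slow + fast)
  expect_equal(mean(high_pass(mixed, tr, 128)), mean(mixed))
  expect_warning(high_pass(matrix(rnorm(40), 2), tr, 128), "skipped")
  expect_error(high_pass(matrix(1, 2, 10), 1, 1.5), "exceed")
})

test_that("global scaling fixes every scan mean at 100 and is idempotent", {
  set.seed(4)
  Y <- matrix(rexp(200) + 1, 10, 20)
  S <- global_scale(Y)
  expect_equal(colMeans(S), rep(100, 20))
  expect_equal(global_scale(S), S)
  expect_equal(global_scale(2 * Y), S)
  expect_error(global_scale(matrix(c(-2, 1), 2, 3)), "non-positive")
})

test_that("noiseless beta series recovers the planted amplitudes", {
  d <- generate_design(seed = 31)
  sim <- simulate_bold_roi(d, quiet_truth(), n_voxels = 10, seed = 8)
  beta <- estimate_beta_series(as_roi_timeseries(sim), d,
                               options = list(global_scale = FALSE))
  rel <- max(abs(beta$betas - sim$truth_betas)) / max(abs(sim$truth_betas))
  expect_lt(rel, 1e-6)
  expect_equal(nrow(beta$betas), 120)
  expect_equal(beta$trials$condition, d$condition)
})

test_that("zero data give zero betas; equal amplitudes give equal betas", {
  d <- generate_design(n_trials = 20, pairing_rate = 0, n_initial_paired = 0,
                       seed = 7)
  n_scans <- ceiling((attr(d, "total_duration_s") + 20) / 1.98)
  roi <- roi_timeseries(matrix(0, 4, n_scans), 1.98)
  beta <- estimate_beta_series(roi, d, options = list(global_scale = FALSE,
                                                      high_pass = FALSE))
  expect_equal(unname(beta$betas), matrix(0, 20, 4))

  truth <- quiet_truth(n_trials = 20, change_point = 20, early_diff = 0,
                       sep_start = 0, sep_end = 0)
  sim <- simulate_bold_roi(d, truth, n_voxels = 5, seed = 2)
  b2 <- estimate_beta_series(as_roi_timeseries(sim), d,
                             options = list(global_scale = FALSE))
  # all trials planted at the same amplitude on a shared pattern
  expect_lt(max(abs(sweep(b2$betas, 2, b2$betas[1, ]))), 1e-8)
})

test_that("beta estimates are unbiased and tighten as noise shrinks", {
  d <- generate_design(n_trials = 30, pairing_rate = 0, n_initial_paired = 0,
                       seed = 13)
  errs <- sapply(1:50, function(r) {
    sim <- simulate_bold_roi(d, quiet_truth(n_trials = 30, change_point = 15),
                             n_voxels = 4, seed = 100 + r)
    noisy <- sim
    set.seed(200 + r)
    noisy$data <- sim$data + matrix(rnorm(length(sim$data), sd = 0.5),
                                    nrow(sim$data))
    b <- estimate_beta_series(as_roi_timeseries(noisy), d,
                              options = list(global_scale = FALSE))
    mean(b$betas - sim$truth_betas)
  })
  ci <- mean(errs) + c(-1, 1) * qt(0.975, length(errs) - 1) * sd(errs) / sqrt(length(errs))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("beta series round-trip through TSV plus sidecar", {
  d <- generate_design(n_trials = 10, pairing_rate = 0, n_initial_paired = 0,
                       seed = 3)
  sim <- simulate_bold_roi(d, quiet_truth(n_trials = 10, change_point = 5),
                           n_voxels = 3, seed = 5)
  beta <- estimate_beta_series(as_roi_timeseries(sim, roi = "insula",
                                                 subject = "sub-07"),
                               d, options = list(global_scale = FALSE,
                                                 high_pass = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_series(beta, path)
  back <- read_beta_series(path)
  expect_equal(unname(back$betas), unname(beta$betas), tolerance = 1e-8)
  expect_equal(back$subject, "sub-07")
  expect_equal(back$roi, "insula")
})
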