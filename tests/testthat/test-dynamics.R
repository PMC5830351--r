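test_that("early/late split uses strict onset < threshold and partitions trials", {
  ts <- data.frame(onset = c(335.9, 336.0, 100, 400),
                   condition = c("CSplus", "CSplus", "CSminus", "CSminus"),
                   value = c(1, 2, 3, 4))
  sp <- split_early_late(ts, t_split_s = 336)
  expect_equal(sp$means["early", "CSplus"], 1)  # 335.9 s is early
  expect_equal(sp$means["late", "CSplus"], 2)   # 336.0 s is late
  expect_equal(sum(sp$counts), nrow(ts))        # every trial in exactly one cell
  expect_error(split_early_late(ts, t_split_s = 50), "early")
})

test_that("identical condition amplitudes give a zero differential", {
  ts <- make_trial_series(rep(2, 30), rep(2, 30))
  sp <- split_early_late(ts, t_split_s = median(ts$onset))
  expect_equal(unname(sp$differential), c(0, 0))
})

test_that("a planted early-only difference orders the period differentials", {
  # difference 1.0 that decays to 0 after trial 60 of 120; noise-free
  tr <- quiet_truth()
  vals_p <- tr$amp_csplus[seq(1, 119, by = 2)]
  vals_m <- tr$amp_csminus[seq(2, 120, by = 2)]
  ts <- make_trial_series(vals_p, vals_m)
  sp <- split_early_late(ts, t_split_s = 336)
  expect_gt(sp$differential["early"], sp$differential["late"])
})

test_that("paired early/late tests apply Benjamini-Hochberg across ROIs", {
  set.seed(10)
  early <- cbind(a = rnorm(12, 1), b = rnorm(12, 0.5), c = rnorm(12))
  late <- cbind(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  res <- early_late_test(early, late)
  # independent BH oracle: sorted p * n / rank, cumulative minimum from the top
  o <- order(res$p)
  adj <- res$p[o] * length(res$p) / seq_along(res$p)
  adj <- rev(cummin(rev(adj)))
  expect_equal(res$p_fdr[o], pmin(adj, 1))
  # per-ROI t equals a direct paired t-test
  ht <- t.test(early[, 1], late[, 1], paired = TRUE)
  expect_equal(res$t[1], unname(ht$statistic))
  expect_equal(res$p[1], ht$p.value)
  expect_error(early_late_test(early[1, , drop = FALSE], late[1, , drop = FALSE]),
               "2 subjects")
})

test_that("identical early and late values give t = 0, p = 1", {
  m <- matrix(rnorm(20), 10, 2)
  res <- early_late_test(m, m)
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("the early/late test is calibrated under the null", {
  set.seed(77)
  rejections <- replicate(1000, {
    e <- matrix(rnorm(18), 18, 1)
    l <- matrix(rnorm(18), 18, 1)
    early_late_test(e, l)$p[1] < 0.05
  })
  expect_gte(mean(rejections), 0.036)
  expect_lte(mean(rejections), 0.064)
})

test_that("the Gaussian smoother reproduces constants and limits to the mean", {
  ts <- make_trial_series(rep(3, 20), rep(3, 20))
  sc <- smooth_curves(ts, bandwidth_trials = 2)
  expect_equal(sc$cs_plus, rep(3, length(sc$time_s)))
  set.seed(5)
  ts2 <- make_trial_series(rnorm(20), rnorm(20))
  big <- smooth_curves(ts2, bandwidth_trials = 1e6)
  expect_equal(big$cs_plus,
               rep(mean(ts2$value[ts2$condition == "CSplus"]), length(big$time_s)),
               tolerance = 1e-6)
  expect_error(smooth_curves(make_trial_series(1:2, 1:2)), "fewer than 3")
  expect_error(smooth_curves(ts, bandwidth_trials = 0), "positive")
})

test_that("the smoother is linear and tracks a step away from its edge", {
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40)
  mk <- function(v) make_trial_series(v[seq(1, 39, 2)], v[seq(2, 40, 2)])
  s1 <- smooth_curves(mk(x), 3)
  s2 <- smooth_curves(mk(y), 3)
  s3 <- smooth_curves(mk(2 * x - 5 * y), 3)
  expect_equal(s3$cs_plus, 2 * s1$cs_plus - 5 * s2$cs_plus, tolerance = 1e-10)
  # step series: plateau levels recovered away from the step and the edges
  step_vals <- c(rep(10, 30), rep(2, 30))
  ts <- make_trial_series(step_vals[seq(1, 59, 2)], step_vals[seq(2, 60, 2)])
  sc <- smooth_curves(ts, bandwidth_trials = 1)
  interior_lo <- sc$time_s > ts$onset[5] & sc$time_s < ts$onset[22]
  interior_hi <- sc$time_s > ts$onset[38] & sc$time_s < ts$onset[55]
  expect_true(all(abs(sc$cs_plus[interior_lo] - 10) < 0.5))
  expect_true(all(abs(sc$cs_plus[interior_hi] - 2) < 0.1))
})

test_that("differencing cancels condition-independent additive drift", {
  set.seed(8)
  base <- make_trial_series(rnorm(30), rnorm(30))
  shifted <- base
  shifted$value <- base$value + 3.7  # constant offset cancels exactly
  d0 <- differential_curve(smooth_curves(base, 5))
  d1 <- differential_curve(smooth_curves(shifted, 5))
  expect_equal(d1$contrast, d0$contrast, tolerance = 1e-12)
  expect_equal(d1$value, d0$value, tolerance = 1e-12)
  # a slowly varying drift cancels approximately (conditions interleave)
  drift <- base
  drift$value <- base$value + 2 * sin(2 * pi * drift$onset / 400)
  d2 <- differential_curve(smooth_curves(drift, 5))
  # residual is ~5% of the drift amplitude, versus 100% without differencing
  expect_lt(max(abs(d2$contrast - d0$contrast)), 0.15)
})

test_that("identical curves give a zero differential everywhere", {
  ts <- make_trial_series(rep(1.5, 25), rep(1.5, 25))
  dc <- differential_curve(smooth_curves(ts, 4))
  expect_equal(dc$value, rep(0, length(dc$value)))
  expect_equal(length(dc$contrast), 25)  # one per CS+ trial
})

test_that("adaptation slope recovers exact lines and flags short input", {
  dc <- structure(list(contrast = rep(2, 10)), class = "diff_curve")
  expect_equal(adaptation_slope(dc), 0)
  dc2 <- structure(list(contrast = 1 - 0.01 * (1:50)), class = "diff_curve")
  expect_equal(adaptation_slope(dc2), -0.01)
  expect_error(adaptation_slope(structure(list(contrast = c(1, 2)),
                                          class = "diff_curve")), "3 points")
})

test_that("a planted declining difference yields negative fitted slopes", {
  set.seed(9)
  signs <- replicate(200, {
    tr <- quiet_truth()
    vals_p <- tr$amp_csplus[seq(1, 119, 2)] + rnorm(60, sd = 0.5)
    vals_m <- tr$amp_csminus[seq(2, 120, 2)] + rnorm(60, sd = 0.5)
    dc <- differential_curve(smooth_curves(make_trial_series(vals_p, vals_m), 5))
    adaptation_slope(dc) < 0
  })
  expect_gte(mean(signs), 0.95)
})

test_that("bandwidth sensitivity reruns the slope at each requested width", {
  set.seed(12)
  tr <- quiet_truth()
  ts <- make_trial_series(tr$amp_csplus[seq(1, 119, 2)],
                          tr$amp_csminus[seq(2, 120, 2)])
  sens <- smoothing_sensitivity(ts, bandwidths = c(3, 5, 8))
  expect_equal(nrow(sens), 3)
  expect_true(all(sens$slope < 0))
})
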