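test_that("window counts follow floor((n - window)/step) + 1", {
  set.seed(1)
  b <- make_beta_series(n_trials = 120, n_voxels = 6,
                        betas = matrix(rnorm(720), 120, 6))
  dc <- window_dissimilarity(b, window = 50, step = 2)
  expect_equal(dc$n_windows, 36)
  b2 <- make_beta_series(n_trials = 60, n_voxels = 6,
                         betas = matrix(rnorm(360), 60, 6))
  expect_equal(window_dissimilarity(b2, window = 20, step = 5)$n_windows, 9)
  expect_error(window_dissimilarity(b2, window = 80), "fewer analysed trials")
})

test_that("identical patterns give D = 0 and orthogonal patterns D = 1", {
  d <- generate_design(seed = 41)
  shared <- simulate_bold_roi(d, quiet_truth(sep_start = 0, sep_end = 0),
                              n_voxels = 12, seed = 1)
  b_shared <- estimate_beta_series(as_roi_timeseries(shared), d,
                                   options = list(global_scale = FALSE))
  dc <- window_dissimilarity(b_shared)
  expect_equal(dc$dissimilarity, rep(0, dc$n_windows), tolerance = 1e-6)

  ortho <- simulate_bold_roi(d, quiet_truth(sep_start = 1, sep_end = 1),
                             n_voxels = 12, seed = 1)
  b_ortho <- estimate_beta_series(as_roi_timeseries(ortho), d,
                                  options = list(global_scale = FALSE))
  do <- window_dissimilarity(b_ortho)
  expect_equal(do$dissimilarity, rep(1, do$n_windows), tolerance = 1e-6)
})

test_that("dissimilarity is bounded and invariant to scalar pattern shifts", {
  set.seed(7)
  b <- make_beta_series(n_trials = 80, n_voxels = 8,
                        betas = matrix(rnorm(80 * 8), 80, 8))
  dc <- window_dissimilarity(b, window = 30, step = 5)
  expect_true(all(dc$dissimilarity >= 0 & dc$dissimilarity <= 2))
  b2 <- b
  b2$betas <- b$betas + 42  # same shift on both condition patterns
  dc2 <- window_dissimilarity(b2, window = 30, step = 5)
  expect_equal(dc2$r, dc$r, tolerance = 1e-10)
})

test_that("a single whole-block window equals the block-level correlation", {
  set.seed(8)
  n <- 40
  b <- make_beta_series(n_trials = n, n_voxels = 10,
                        betas = matrix(rnorm(n * 10), n, 10))
  dc <- window_dissimilarity(b, window = n, step = 2)
  expect_equal(dc$n_windows, 1)
  is_plus <- b$trials$condition == "CSplus_unpaired"
  r_oracle <- cor(colMeans(b$betas[is_plus, ]), colMeans(b$betas[!is_plus, ]))
  expect_equal(dc$r, r_oracle)
  expect_equal(dc$dissimilarity, 1 - r_oracle)
})

test_that("voxel guards fire for tiny patterns", {
  b <- make_beta_series(n_trials = 20, n_voxels = 3,
                        betas = matrix(rnorm(60), 20, 3))
  expect_warning(window_dissimilarity(b, window = 10, step = 5), "4 voxels")
  b2 <- make_beta_series(n_trials = 20, n_voxels = 2,
                         betas = matrix(rnorm(40), 20, 2))
  expect_error(suppressWarnings(window_dissimilarity(b2, window = 10, step = 5)),
               "3 voxels")
})

test_that("zero-variance windows are recorded as missing with a warning", {
  b <- make_beta_series(n_trials = 20, n_voxels = 6,
                        betas = matrix(1, 20, 6))  # flat patterns
  expect_warning(dc <- window_dissimilarity(b, window = 10, step = 5),
                 "zero-variance")
  expect_true(all(is.na(dc$dissimilarity)))
})

test_that("group Fisher-z averaging has the stated fixed points", {
  mk <- function(r) new_curve <- structure(
    list(window_center_trial = 1:5, window_center_s = 1:5 * 5,
         r = rep(r, 5), dissimilarity = 1 - rep(r, 5),
         window = 10L, step = 2L, n_windows = 5L,
         subject = "s", roi = "roi", n_subjects = 1L),
    class = "dissim_curve")
  g <- group_curve(list(mk(0.5), mk(0.5)))
  expect_equal(g$dissimilarity, rep(0.5, 5))          # fixed point
  g2 <- group_curve(list(mk(0.8), mk(-0.8)))
  expect_equal(g2$dissimilarity, rep(1, 5))           # antisymmetry of atanh
  # Jensen gap: z-averaging differs from naive averaging of 1 - r
  g3 <- group_curve(list(mk(0.2), mk(0.9)))
  naive <- 1 - mean(c(0.2, 0.9))
  zavg <- 1 - tanh(mean(atanh(c(0.2, 0.9))))
  expect_equal(g3$dissimilarity, rep(zavg, 5))
  expect_false(isTRUE(all.equal(g3$dissimilarity[1], naive)))
  # perfect correlations are clipped before the transform
  expect_warning(group_curve(list(mk(1), mk(0.5))), "clipped")
  expect_error(group_curve(list(mk(0.5))), "2 subjects")
})

test_that("dissimilarity slopes recover exact lines", {
  mk_curve <- function(D) structure(
    list(dissimilarity = D, n_windows = length(D)), class = "dissim_curve")
  expect_equal(dissimilarity_slope(mk_curve(rep(0.4, 20))), 0)
  expect_equal(dissimilarity_slope(mk_curve(1 - 0.002 * (1:30))), -0.002)
  expect_error(dissimilarity_slope(mk_curve(c(1, 2))), "3 windows")
})

test_that("endpoint test is null for flat curves and errors on short curves", {
  mk_curve <- function(D) structure(
    list(dissimilarity = D, n_windows = length(D)), class = "dissim_curve")
  flat <- lapply(1:6, function(i) mk_curve(rep(0.5, 25)))
  res <- endpoint_test(flat, k = 10)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(endpoint_test(lapply(1:3, function(i) mk_curve(rep(0.5, 15))),
                             k = 10), "2k windows")
})

test_that("endpoint test is calibrated under a null with curve noise", {
  set.seed(21)
  rejections <- replicate(1000, {
    curves <- lapply(1:12, function(i) structure(
      list(dissimilarity = 0.5 + rnorm(30, sd = 0.05), n_windows = 30L),
      class = "dissim_curve"))
    endpoint_test(curves, k = 10)$p < 0.05
  })
  expect_gte(mean(rejections), 0.036)
  expect_lte(mean(rejections), 0.064)
})

test_that("planted pattern convergence drives D down and the slope negative", {
  d <- generate_design(seed = 51)
  sim <- simulate_bold_roi(d, quiet_truth(sep_start = 1, sep_end = 0),
                           n_voxels = 16, seed = 3)
  b <- estimate_beta_series(as_roi_timeseries(sim), d,
                            options = list(global_scale = FALSE))
  dc <- window_dissimilarity(b)
  expect_gt(dc$dissimilarity[1], tail(dc$dissimilarity, 1))
  expect_lt(dissimilarity_slope(dc), 0)
})

test_that("dissimilarity curves export the documented TSV columns", {
  b <- make_beta_series(n_trials = 30, n_voxels = 5,
                        betas = matrix(rnorm(150), 30, 5))
  dc <- window_dissimilarity(b, window = 10, step = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dissim_curve(dc, path)
  back <- read.delim(path)
  expect_equal(names(back),
               c("window_center_trial", "window_center_s", "r", "dissimilarity"))
  expect_equal(back$dissimilarity, dc$dissimilarity)
})
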