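#' Sliding-window dissimilarity between CS+ and CS- voxel patterns
#'
#' Slides a window over the chronological sequence of analysed trials
#' (unreinforced CS+ and CS-; reinforced trials are excluded before
#' windowing). Within each window the voxel patterns are averaged per
#' condition, the two mean patterns are Pearson-correlated across voxels,
#' and the dissimilarity `D = 1 - r` is recorded. Defaults follow the
#' 50-trial window with 2-trial steps, giving
#' `floor((n - window)/step) + 1` windows.
#'
#' The beta series should come from spatially unsmoothed data so fine-scale
#' pattern information is preserved.
#'
#' @param beta A `beta_series`.
#' @param window Window length in analysed trials; default 50.
#' @param step Step size in analysed trials; default 2.
#' @param min_per_cond Minimum trials of each condition per window.
#' @return An object of class `dissim_curve`: `window_center_trial`
#'   (original trial indices), `window_center_s`, `r`, `dissimilarity`,
#'   window/step and subject/roi ids. Windows with a zero-variance pattern
#'   are recorded as missing with a warning.
#' @export
window_dissimilarity <- function(beta, window = 50L, step = 2L,
                                 min_per_cond = 3L) {
  keep <- beta$trials$condition %in% c("CSplus_unpaired", "CSminus")
  tr <- beta$trials[keep, , drop = FALSE]
  B <- beta$betas[keep, , drop = FALSE]
  n <- nrow(B)
  n_vox <- ncol(B)
  if (n_vox < 3L) stop("need at least 3 voxels for pattern correlation")
  if (n_vox < 4L) {
    warning("fewer than 4 voxels: pattern dissimilarity will be unreliable")
  }
  if (n < window) stop("fewer analysed trials than the window length")
  is_plus <- tr$condition == "CSplus_unpaired"

  starts <- seq(1L, n - window + 1L, by = step)
  r <- numeric(length(starts))
  ctr_trial <- numeric(length(starts))
  ctr_s <- numeric(length(starts))
  warned <- FALSE
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + window - 1L)
    wp <- idx[is_plus[idx]]
    wm <- idx[!is_plus[idx]]
    if (length(wp) < min_per_cond || length(wm) < min_per_cond) {
      stop(sprintf("window %d has fewer than %d trials of one condition",
                   w, min_per_cond))
    }
    mp <- colMeans(B[wp, , drop = FALSE])
    mm <- colMeans(B[wm, , drop = FALSE])
    if (stats::sd(mp) == 0 || stats::sd(mm) == 0) {
      r[w] <- NA_real_
      warned <- TRUE
    } else {
      r[w] <- stats::cor(mp, mm)
    }
    ctr_trial[w] <- mean(tr$trial[idx])
    ctr_s[w] <- mean(tr$onset[idx])
  }
  if (warned) warning("zero-variance pattern in some window(s): dissimilarity recorded as missing")
  new_dissim_curve(ctr_trial, ctr_s, r, window, step,
                   subject = beta$subject, roi = beta$roi)
}

new_dissim_curve <- function(center_trial, center_s, r, window, step,
                             subject, roi, n_subjects = 1L) {
  structure(list(window_center_trial = center_trial,
                 window_center_s = center_s,
                 r = r,
                 dissimilarity = 1 - r,
                 window = as.integer(window),
                 step = as.integer(step),
                 n_windows = length(r),
                 subject = subject, roi = roi,
                 n_subjects = n_subjects),
            class = "dissim_curve")
}

#' @export
print.dissim_curve <- function(x, ...) {
  cat(sprintf("<dissim_curve> %s / %s: %d windows (length %d, step %d), D in [%.3g, %.3g]\n",
              x$subject, x$roi, x$n_windows, x$window, x$step,
              min(x$dissimilarity, na.rm = TRUE), max(x$dissimilarity, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.dissim_curve <- function(x, ...) {
  graphics::plot(x$window_center_trial, x$dissimilarity, type = "l",
                 xlab = "window center (trial)", ylab = "dissimilarity (1 - r)", ...)
  invisible(x)
}

#' Group dissimilarity curve by Fisher-z averaging
#'
#' Per window, the subjects' correlations are Fisher-z transformed
#' (`atanh`), averaged, transformed back (`tanh`), and subtracted from 1.
#' Averaging on the z scale respects the sampling distribution of
#' correlation coefficients; the result differs from naively averaging
#' `1 - r` whenever subjects disagree.
#'
#' @param curves List of `dissim_curve` objects with matching window
#'   layouts — same window length, step and window count — so windows align
#'   by index (>= 2 subjects). Window centers are averaged across subjects.
#' @param clip Correlations at exactly +/-1 are clipped to
#'   `+/-(1 - clip)` with a warning before the transform.
#' @return A group-level `dissim_curve` (subject `"group"`).
#' @export
group_curve <- function(curves, clip = 1e-6) {
  if (length(curves) < 2L) stop("need at least 2 subjects")
  same <- vapply(curves[-1], function(cu) {
    cu$window == curves[[1]]$window && cu$step == curves[[1]]$step &&
      cu$n_windows == curves[[1]]$n_windows
  }, logical(1))
  if (!all(same)) stop("subjects have different window layouts")
  R <- do.call(rbind, lapply(curves, `[[`, "r"))
  if (any(abs(R) >= 1, na.rm = TRUE)) {
    warning("correlation(s) at +/-1 clipped before Fisher-z transform")
    R[R >= 1] <- 1 - clip
    R[R <= -1] <- -(1 - clip)
  }
  rbar <- tanh(colMeans(atanh(R)))
  ctr_trial <- colMeans(do.call(rbind, lapply(curves, `[[`, "window_center_trial")))
  ctr_s <- colMeans(do.call(rbind, lapply(curves, `[[`, "window_center_s")))
  new_dissim_curve(ctr_trial, ctr_s,
                   rbar, curves[[1]]$window, curves[[1]]$step,
                   subject = "group", roi = curves[[1]]$roi,
                   n_subjects = length(curves))
}

#' Endpoint test of dissimilarity curves
#'
#' Compares, across subjects, the mean dissimilarity of the first `k`
#' windows against the last `k` windows with a two-sided paired t-test. A
#' positive difference (first > last) indicates pattern convergence.
#'
#' @param curves List of per-subject `dissim_curve` objects, each with at
#'   least `2k` windows.
#' @param k Number of windows at each end; default 10.
#' @return A list: `t`, `df`, `p`, `mean_first`, `mean_last`, `k`.
#' @export
endpoint_test <- function(curves, k = 10L) {
  if (length(curves) < 2L) stop("need at least 2 subjects")
  ends <- vapply(curves, function(cu) {
    D <- cu$dissimilarity
    if (length(D) < 2L * k) stop("curve has fewer than 2k windows")
    c(mean(D[seq_len(k)], na.rm = TRUE),
      mean(D[(length(D) - k + 1L):length(D)], na.rm = TRUE))
  }, numeric(2))
  first <- ends[1, ]
  last <- ends[2, ]
  if (stats::sd(first - last) == 0) {
    return(list(t = 0, df = length(first) - 1L, p = 1,
                mean_first = mean(first), mean_last = mean(last), k = k))
  }
  ht <- stats::t.test(first, last, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_first = mean(first), mean_last = mean(last), k = k)
}

#' Slope of a dissimilarity curve
#'
#' Ordinary-least-squares slope of dissimilarity against window index
#' (windows are equally spaced in trials). Negative slopes indicate that
#' the CS+ and CS- patterns converge over acquisition.
#'
#' @param curve A `dissim_curve` with at least 3 non-missing windows.
#' @return Slope (dissimilarity units per window step).
#' @export
dissimilarity_slope <- function(curve) {
  D <- curve$dissimilarity
  idx <- seq_along(D)
  ok <- !is.na(D)
  if (sum(ok) < 3L) stop("need at least 3 windows for a slope")
  unname(stats::coef(stats::lm(D[ok] ~ idx[ok]))[2])
}

#' Write a dissimilarity curve as TSV
#'
#' Columns: `window_center_trial`, `window_center_s`, `r`, `dissimilarity`.
#'
#' @param curve A `dissim_curve`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dissim_curve <- function(curve, path) {
  df <- data.frame(window_center_trial = curve$window_center_trial,
                   window_center_s = curve$window_center_s,
                   r = curve$r,
                   dissimilarity = curve$dissimilarity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
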