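#' Per-trial response series from a beta series
#'
#' Collapses a beta series to one value per analysed trial (ROI mean across
#' voxels), excluding reinforced CS+ trials, and collapses conditions to
#' CS+/CS-. This is the input representation shared by the univariate
#' dynamics functions, which also accept any data.frame with `onset`,
#' `condition` and `value` columns (e.g., per-trial heart-rate responses).
#'
#' @param beta A `beta_series`.
#' @return A data.frame (`trial`, `onset`, `condition`, `value`) of class
#'   `trial_series`.
#' @export
beta_trial_series <- function(beta) {
  keep <- beta$trials$condition %in% c("CSplus_unpaired", "CSminus")
  tr <- beta$trials[keep, , drop = FALSE]
  out <- data.frame(trial = tr$trial,
                    onset = tr$onset,
                    condition = ifelse(tr$condition == "CSminus",
                                       "CSminus", "CSplus"),
                    value = rowMeans(beta$betas[keep, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_series", "data.frame")
  out
}

as_trial_series <- function(x) {
  if (inherits(x, "beta_series")) return(beta_trial_series(x))
  if (!is.data.frame(x) || !all(c("onset", "condition", "value") %in% names(x))) {
    stop("expected a beta_series or a data.frame with onset/condition/value")
  }
  x <- x[x$condition %in% c("CSplus", "CSminus", "CSplus_unpaired"), , drop = FALSE]
  x$condition <- ifelse(x$condition == "CSminus", "CSminus", "CSplus")
  if (is.null(x$trial)) x$trial <- seq_len(nrow(x))
  x
}

#' Early/late period means of the differential response
#'
#' Splits the block at `t_split_s` seconds of time-on-task (trials with onset
#' strictly before the split are "early"), averages the per-trial values by
#' condition within each period, and returns the CS+ minus CS- differential
#' per period. The 336-s default is the 5.6-min demarcation of a ~12-min
#' block; splitting on time rather than trial count avoids biasing the
#' periods toward either stimulus type.
#'
#' @param x A `beta_series` or trial-series data.frame.
#' @param t_split_s Split time (s).
#' @return A list with `means` (2 x 2 period-by-condition matrix),
#'   `differential` (named vector, early and late CS+ minus CS-), `t_split_s`
#'   and per-cell trial counts.
#' @export
split_early_late <- function(x, t_split_s = 336) {
  ts <- as_trial_series(x)
  period <- ifelse(ts$onset < t_split_s, "early", "late")
  means <- matrix(NA_real_, 2, 2,
                  dimnames = list(c("early", "late"), c("CSplus", "CSminus")))
  counts <- means
  for (p in rownames(means)) {
    for (cond in colnames(means)) {
      v <- ts$value[period == p & ts$condition == cond]
      if (!length(v)) {
        stop(sprintf("no %s trials in the %s period", cond, p))
      }
      means[p, cond] <- mean(v)
      counts[p, cond] <- length(v)
    }
  }
  list(means = means,
       differential = c(early = means["early", "CSplus"] - means["early", "CSminus"],
                        late = means["late", "CSplus"] - means["late", "CSminus"]),
       counts = counts,
       t_split_s = t_split_s)
}

#' Early-versus-late paired tests across subjects, with FDR correction
#'
#' For each region of interest, a two-sided paired t-test of the per-subject
#' early differential against the late differential, with Benjamini-Hochberg
#' adjustment across the ROI set.
#'
#' @param early,late Numeric subjects x ROIs matrices of differential
#'   responses (same dimensions, matching columns).
#' @return A data.frame with one row per ROI: mean early/late differential,
#'   `t`, `df`, `p`, and BH-adjusted `p_fdr`.
#' @export
early_late_test <- function(early, late) {
  early <- as.matrix(early)
  late <- as.matrix(late)
  if (!all(dim(early) == dim(late))) stop("'early' and 'late' must match in shape")
  if (nrow(early) < 2L) stop("need at least 2 subjects for a paired t-test")
  rois <- colnames(early) %||% paste0("roi", seq_len(ncol(early)))
  tests <- lapply(seq_len(ncol(early)), function(j) {
    d <- early[, j] - late[, j]
    if (stats::sd(d) == 0) {
      list(statistic = 0, parameter = nrow(early) - 1L, p.value = 1)
    } else {
      stats::t.test(early[, j], late[, j], paired = TRUE)
    }
  })
  out <- data.frame(
    roi = rois,
    mean_early = colMeans(early),
    mean_late = colMeans(late),
    t = vapply(tests, function(h) unname(h$statistic), numeric(1)),
    df = vapply(tests, function(h) unname(h$parameter), numeric(1)),
    p = vapply(tests, function(h) h$p.value, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

# Nadaraya-Watson Gaussian kernel smoother; weights renormalised at the
# edges (no padding), so a constant series is reproduced exactly.
nw_smooth <- function(x, y, xout, sd) {
  vapply(xout, function(x0) {
    w <- exp(-(x - x0)^2 / (2 * sd^2))
    sum(w * y) / sum(w)
  }, numeric(1))
}

#' Gaussian-smoothed condition response curves
#'
#' Smooths each condition's per-trial values against trial onset time with a
#' Nadaraya-Watson Gaussian kernel, evaluated on a grid shared by both
#' conditions. The kernel SD is `bandwidth_trials` times the mean spacing of
#' the analysed trials, i.e., the bandwidth is expressed in trial-time units.
#'
#' @param x A `beta_series` or trial-series data.frame.
#' @param bandwidth_trials Kernel SD in trials (> 0); default 5.
#' @param grid Optional evaluation grid (s); default: the analysed trial
#'   onsets.
#' @return An object of class `cond_curves`: `time_s`, `cs_plus`,
#'   `cs_minus`, the bandwidth (trials and seconds) and the underlying trial
#'   series.
#' @export
smooth_curves <- function(x, bandwidth_trials = 5, grid = NULL) {
  if (bandwidth_trials <= 0) stop("'bandwidth_trials' must be positive")
  ts <- as_trial_series(x)
  for (cond in c("CSplus", "CSminus")) {
    if (sum(ts$condition == cond) < 3L) {
      stop("fewer than 3 ", cond, " trials: cannot smooth")
    }
  }
  spacing <- mean(diff(sort(ts$onset)))
  sd_s <- bandwidth_trials * spacing
  if (is.null(grid)) grid <- sort(ts$onset)
  plus <- ts[ts$condition == "CSplus", ]
  minus <- ts[ts$condition == "CSminus", ]
  structure(list(time_s = grid,
                 cs_plus = nw_smooth(plus$onset, plus$value, grid, sd_s),
                 cs_minus = nw_smooth(minus$onset, minus$value, grid, sd_s),
                 bandwidth_trials = bandwidth_trials,
                 bandwidth_s = sd_s,
                 series = ts),
            class = "cond_curves")
}

#' Differential (CS+ minus CS-) response curve
#'
#' Pointwise difference of the smoothed condition curves, plus the per-trial
#' contrast series used by the change-point analysis: at each unreinforced
#' CS+ trial onset, the smoothed CS+ value minus the smoothed CS- value.
#' Differencing removes condition-independent, slowly varying influences
#' (arousal, scanner drift) that both conditions share.
#'
#' @param curves A `cond_curves` from [smooth_curves()].
#' @return An object of class `diff_curve`: `time_s`, `value`
#'   (CS+ minus CS- on the grid), `contrast` (per-CS+-trial series),
#'   `contrast_onsets` and `contrast_trials` (original trial indices).
#' @export
differential_curve <- function(curves) {
  ts <- curves$series
  plus <- ts[ts$condition == "CSplus", ]
  minus <- ts[ts$condition == "CSminus", ]
  sd_s <- curves$bandwidth_s
  contrast <- nw_smooth(plus$onset, plus$value, plus$onset, sd_s) -
    nw_smooth(minus$onset, minus$value, plus$onset, sd_s)
  structure(list(time_s = curves$time_s,
                 value = curves$cs_plus - curves$cs_minus,
                 contrast = contrast,
                 contrast_onsets = plus$onset,
                 contrast_trials = plus$trial,
                 bandwidth_trials = curves$bandwidth_trials),
            class = "diff_curve")
}

#' @export
print.diff_curve <- function(x, ...) {
  cat(sprintf("<diff_curve> %d grid points, %d CS+ trials; mean %.3g, slope %.3g/trial\n",
              length(x$time_s), length(x$contrast),
              mean(x$value), adaptation_slope(x)))
  invisible(x)
}

#' @export
plot.diff_curve <- function(x, ...) {
  graphics::plot(x$time_s, x$value, type = "l",
                 xlab = "time (s)", ylab = "CS+ minus CS- response", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Adaptation slope of a differential curve
#'
#' Ordinary-least-squares slope of the per-trial contrast series against
#' trial index: the rate at which the CS+ minus CS- response changes per
#' trial. Negative slopes indicate adaptation.
#'
#' @param curve A `diff_curve`.
#' @return Slope (response units per trial).
#' @export
adaptation_slope <- function(curve) {
  y <- curve$contrast
  if (length(y) < 3L) stop("need at least 3 points for a slope")
  idx <- seq_along(y)
  unname(stats::coef(stats::lm(y ~ idx))[2])
}

#' Smoothing-bandwidth sensitivity of the adaptation analysis
#'
#' Re-runs the smoothing, differential curve and slope at several kernel
#' bandwidths.
#'
#' @param x A `beta_series` or trial-series data.frame.
#' @param bandwidths Kernel SDs in trials.
#' @return A data.frame with one row per bandwidth: the adaptation slope and
#'   the mean differential.
#' @export
smoothing_sensitivity <- function(x, bandwidths = c(3, 5, 8)) {
  rows <- lapply(bandwidths, function(b) {
    dc <- differential_curve(smooth_curves(x, bandwidth_trials = b))
    data.frame(bandwidth_trials = b,
               slope = adaptation_slope(dc),
               mean_differential = mean(dc$contrast))
  })
  do.call(rbind, rows)
}
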