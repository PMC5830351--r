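#' CUSUM chart of a contrast series
#'
#' Cumulative sum of deviations from the series mean: `S_0 = 0`,
#' `S_i = S_{i-1} + (x_i - mean(x))`. An upward (downward) slope marks a
#' stretch where values sit above (below) the overall average, and a change
#' of direction marks a shift in the mean. By construction `S_n = 0`.
#'
#' @param values Numeric series, length >= 3, no missing values.
#' @return Numeric vector `S_0 .. S_n` (length `n + 1`).
#' @examples
#' cusum_chart(c(1, 1, 1, -1, -1, -1))  # 0 1 2 3 2 1 0
#' @export
cusum_chart <- function(values) {
  if (anyNA(values)) stop("missing values in the contrast series")
  if (length(values) < 3L) stop("need at least 3 values")
  c(0, cumsum(values - mean(values)))
}

#' Magnitude of change of a CUSUM chart
#'
#' `max(S) - min(S)`; the test statistic of the permutation procedure.
#'
#' @param cusum A chart from [cusum_chart()].
#' @return Non-negative scalar.
#' @export
change_magnitude <- function(cusum) {
  max(cusum) - min(cusum)
}

#' Permutation confidence level for a change
#'
#' Randomly reorders the series `n_permutations` times, recomputes the
#' magnitude of change each time, and reports the percentage of permuted
#' magnitudes strictly smaller than the observed one. A change is declared
#' significant when the confidence exceeds the threshold (conventionally
#' 95%); ties count against significance.
#'
#' @param values Numeric series, length >= 5.
#' @param n_permutations Number of reorderings (>= 100); default 1000.
#' @param seed Seed for the permutation stream.
#' @return Confidence in percent (0-100).
#' @export
permutation_confidence <- function(values, n_permutations = 1000L, seed) {
  if (length(values) < 5L) stop("need at least 5 values")
  if (n_permutations < 100L) stop("'n_permutations' must be >= 100")
  if (stats::sd(values) == 0) {
    warning("constant series: no variation to permute")
    return(0)
  }
  if (!missing(seed)) set.seed(as.integer(seed))
  xc <- values - mean(values)
  n <- length(xc)
  obs <- {
    s <- cumsum(xc)
    max(s, 0) - min(s, 0)
  }
  perm <- vapply(seq_len(n_permutations), function(b) {
    s <- cumsum(xc[sample.int(n)])
    max(s, 0) - min(s, 0)
  }, numeric(1))
  100 * sum(perm < obs) / n_permutations
}

#' CUSUM estimator of the change point
#'
#' The index at which the CUSUM chart is farthest from zero (maximum of
#' `|S_i|` over `i = 1 .. n-1`), i.e., the last trial before the estimated
#' mean shift. The absolute value handles both rising and declining series;
#' ties break toward the earliest index. Reported 1-based.
#'
#' @param values Numeric series.
#' @return 1-based trial index in `[1, n - 1]`.
#' @export
estimate_change_point <- function(values) {
  S <- cusum_chart(values)
  inner <- abs(S[2:(length(S) - 1L)])  # S_1 .. S_{n-1}
  if (max(inner) == 0) stop("no change point: CUSUM chart is identically zero")
  which.max(inner)
}

#' Change-point detection by CUSUM chart and permutation test
#'
#' Bundles [cusum_chart()], [change_magnitude()], [permutation_confidence()]
#' and [estimate_change_point()] into one analysis of a per-trial contrast
#' series.
#'
#' @param values Per-trial contrast series (e.g., the `contrast` component
#'   of a [differential_curve()]).
#' @param n_permutations Number of permutations; default 1000.
#' @param threshold Confidence threshold in percent; default 95.
#' @param seed Seed for the permutation stream (recorded in the result).
#' @return An object of class `cusum_cp` with the chart, magnitude,
#'   confidence, significance flag and estimated change point.
#' @export
cusum_test <- function(values, n_permutations = 1000L, threshold = 95, seed = 1L) {
  S <- cusum_chart(values)
  mag <- change_magnitude(S)
  conf <- if (stats::sd(values) == 0) {
    warning("constant series: no variation to permute")
    0
  } else {
    permutation_confidence(values, n_permutations, seed = seed)
  }
  cp <- if (mag > 0) estimate_change_point(values) else NA_integer_
  structure(list(values = values, cusum = S, magnitude = mag,
                 confidence = conf, significant = conf > threshold,
                 change_point = cp, threshold = threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "cusum_cp")
}

#' @export
print.cusum_cp <- function(x, ...) {
  cat(sprintf("<cusum_cp> n = %d: change point at trial %s, magnitude %.3g\n",
              length(x$values), x$change_point, x$magnitude))
  cat(sprintf("  confidence %.1f%% (%d permutations, threshold %g%%): %s\n",
              x$confidence, x$n_permutations, x$threshold,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
plot.cusum_cp <- function(x, ...) {
  graphics::plot(seq_along(x$cusum) - 1L, x$cusum, type = "l",
                 xlab = "trial", ylab = "cumulative sum", ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.na(x$change_point)) graphics::abline(v = x$change_point, col = 2, lty = 2)
  invisible(x)
}
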