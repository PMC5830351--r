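#' Instantaneous heart rate from RR intervals
#'
#' Piecewise-constant rate function equal to `60 / RR_i` (beats/min) over the
#' span of interval `i`. Intervals outside the physiological guard range are
#' flagged, replaced by linear interpolation from the neighbouring valid
#' intervals, and reported in the result so artefactual beats cannot distort
#' stimulus-locked averages.
#'
#' @param rr An `rr_series`, a numeric vector of intervals (s), or a list
#'   with `beat_times`.
#' @param guard Physiological interval range (s); default `c(0.2, 3)`.
#' @return An object of class `inst_hr`: `breaks` (time points bounding each
#'   interval, starting at 0), `rates` (beats/min per interval),
#'   `duration_s`, and the indices of interpolated intervals.
#' @export
instantaneous_hr <- function(rr, guard = c(0.2, 3)) {
  intervals <- if (inherits(rr, "rr_series")) {
    rr$intervals
  } else if (is.list(rr) && !is.null(rr$beat_times)) {
    diff(c(0, rr$beat_times))
  } else {
    as.numeric(rr)
  }
  if (length(intervals) < 2L) stop("need at least 2 beats")
  bad <- which(intervals < guard[1] | intervals > guard[2])
  if (length(bad)) {
    ok <- setdiff(seq_along(intervals), bad)
    if (length(ok) < 2L) stop("too few valid RR intervals")
    intervals[bad] <- stats::approx(ok, intervals[ok], xout = bad, rule = 2)$y
    warning(length(bad), " RR interval(s) outside [", guard[1], ", ", guard[2],
            "] s interpolated from neighbours")
  }
  breaks <- cumsum(c(0, intervals))
  structure(list(breaks = breaks,
                 rates = 60 / intervals,
                 duration_s = breaks[length(breaks)],
                 interpolated = bad),
            class = "inst_hr")
}

#' @export
print.inst_hr <- function(x, ...) {
  cat(sprintf("<inst_hr> %d intervals over %.1f s, mean %.1f bpm\n",
              length(x$rates), x$duration_s, mean(x$rates)))
  invisible(x)
}

#' Weighted-bin heart rate around a stimulus onset
#'
#' Divides the window around an onset into fixed-width bins and computes the
#' exact time-weighted mean rate per bin: each instantaneous-rate segment
#' contributes in proportion to the fraction of the bin it occupies. For a
#' piecewise-constant rate this equals the analytic time average.
#'
#' @param hr An `inst_hr`.
#' @param onset_s Stimulus onset (s).
#' @param window Window relative to onset (s); default `c(-1, 5)`.
#' @param bin_s Bin width (s); default 1.
#' @return Named numeric vector of bin values (bpm), one per bin.
#' @export
weighted_bin <- function(hr, onset_s, window = c(-1, 5), bin_s = 1) {
  lo <- onset_s + window[1]
  hi <- onset_s + window[2]
  if (lo < hr$breaks[1] || hi > hr$duration_s) {
    stop("bin window extends beyond the heart-rate recording")
  }
  edges <- seq(lo, hi, by = bin_s)
  if (abs(edges[length(edges)] - hi) > 1e-9) {
    stop("window length must be a whole number of bins")
  }
  # integral of the step function up to t is piecewise linear in t
  cumint <- c(0, cumsum(hr$rates * diff(hr$breaks)))
  I <- stats::approx(hr$breaks, cumint, xout = edges, ties = "ordered")$y
  vals <- diff(I) / bin_s
  names(vals) <- sprintf("bin_%g_%g", window[1] + bin_s * (seq_along(vals) - 1L),
                         window[1] + bin_s * seq_along(vals))
  vals
}

#' Stimulus-locked heart-rate change curves per trial
#'
#' Applies [weighted_bin()] at every analysed trial onset (reinforced CS+
#' trials excluded) and baseline-corrects each trial by subtracting its
#' prestimulus bin.
#'
#' @param rr An `rr_series` (or anything [instantaneous_hr()] accepts).
#' @param design An `fc_design`.
#' @param window,bin_s Bin window and width, as in [weighted_bin()]; the
#'   first bin must be the prestimulus baseline.
#' @param guard Physiological guard range passed to [instantaneous_hr()].
#' @return An object of class `hr_trials`: `hr` (trials x bins, bpm),
#'   `change` (baseline-corrected), `trials` (the analysed design rows),
#'   `window`, `bin_s`.
#' @export
trial_hr_curves <- function(rr, design, window = c(-1, 5), bin_s = 1,
                            guard = c(0.2, 3)) {
  hr <- if (inherits(rr, "inst_hr")) rr else instantaneous_hr(rr, guard = guard)
  tr <- analysed_trials(design)
  mats <- t(vapply(tr$onset, function(on) weighted_bin(hr, on, window, bin_s),
                   numeric(round((window[2] - window[1]) / bin_s))))
  change <- mats - mats[, 1L]
  structure(list(hr = mats, change = change, trials = tr,
                 window = window, bin_s = bin_s),
            class = "hr_trials")
}

#' @export
print.hr_trials <- function(x, ...) {
  cat(sprintf("<hr_trials> %d trials x %d bins (%g s each)\n",
              nrow(x$hr), ncol(x$hr), x$bin_s))
  invisible(x)
}

#' Write an HR trial matrix as TSV
#'
#' Columns: `trial_index`, `condition`, the raw bins, then the
#' baseline-corrected change bins (suffix `_chg`).
#'
#' @param htm An `hr_trials`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hr_trials <- function(htm, path) {
  chg <- htm$change
  colnames(chg) <- paste0(colnames(htm$hr), "_chg")
  df <- data.frame(trial_index = htm$trials$trial,
                   condition = htm$trials$condition,
                   htm$hr, chg, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Temporal dynamics of the heart-rate conditioning effect
#'
#' Summarises each trial by its mean baseline-corrected change over a
#' deceleration window (default 1-4 s post-onset, where the orienting
#' deceleration peaks), then reuses the univariate dynamics machinery:
#' early/late split, Gaussian-smoothed condition curves and the CS+ minus
#' CS- differential curve. Also exports the per-subject acquisition-mean
#' difference (mean CS+ minus mean CS- scalar response), the covariate used
#' by the change-point concordance analysis.
#'
#' @param htm An `hr_trials`.
#' @param decel_window Post-onset window (s) averaged into the per-trial
#'   scalar; bins fully inside it are used.
#' @param bandwidth_trials Kernel SD (trials) for the smoothed curves.
#' @param t_split_s Early/late demarcation (s).
#' @return A list of class `hr_dynamics`: `series` (per-trial scalar
#'   responses), `split` (early/late summary), `curve` (the differential
#'   [diff_curve]), `acq_diff` (acquisition-mean CS+ minus CS- difference,
#'   bpm), and the settings.
#' @export
hr_dynamics <- function(htm, decel_window = c(1, 4), bandwidth_trials = 5,
                        t_split_s = 336) {
  lowers <- htm$window[1] + htm$bin_s * (seq_len(ncol(htm$change)) - 1L)
  uppers <- lowers + htm$bin_s
  use <- lowers >= decel_window[1] - 1e-9 & uppers <= decel_window[2] + 1e-9
  if (!any(use)) stop("no bins fall inside the deceleration window")
  scalar <- rowMeans(htm$change[, use, drop = FALSE])
  series <- data.frame(trial = htm$trials$trial,
                       onset = htm$trials$onset,
                       condition = ifelse(htm$trials$condition == "CSminus",
                                          "CSminus", "CSplus"),
                       value = scalar,
                       stringsAsFactors = FALSE)
  split <- split_early_late(series, t_split_s = t_split_s)
  curve <- differential_curve(smooth_curves(series, bandwidth_trials))
  acq_diff <- mean(series$value[series$condition == "CSplus"]) -
    mean(series$value[series$condition == "CSminus"])
  structure(list(series = series, split = split, curve = curve,
                 acq_diff = acq_diff, decel_window = decel_window,
                 bandwidth_trials = bandwidth_trials, t_split_s = t_split_s),
            class = "hr_dynamics")
}

#' @export
print.hr_dynamics <- function(x, ...) {
  cat(sprintf("<hr_dynamics> acquisition-mean CS+ minus CS- change: %.2f bpm\n",
              x$acq_diff))
  cat(sprintf("  early differential %.2f, late %.2f bpm\n",
              x$split$differential["early"], x$split$differential["late"]))
  invisible(x)
}
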