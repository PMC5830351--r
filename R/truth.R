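#' Ground truth for the synthetic forward models
#'
#' Encodes the effects the downstream analyses are meant to recover: a
#' per-trial BOLD amplitude for each condition (with a planted change point in
#' the CS+ minus CS- difference), a per-trial multivoxel pattern-separation
#' coefficient, drift/noise levels, a US response amplitude, and the
#' stimulus-locked heart-rate deceleration per condition.
#'
#' `planted_truth()` builds an acquisition-style truth: the condition
#' difference holds at `early_diff` up to trial `change_point`, then declines
#' linearly to `late_diff` by the last trial; pattern separation decays
#' linearly from `sep_start` to `sep_end`; the heart-rate deceleration
#' difference is modulated by the same normalised decline. `null_truth()`
#' builds a habituation-style truth with no condition difference anywhere.
#'
#' @param n_trials Number of trials the truth describes.
#' @param change_point 1-based trial index at which the CS+ minus CS-
#'   amplitude difference begins to decline.
#' @param early_diff,late_diff Amplitude difference (arbitrary BOLD units)
#'   before the change point and at the final trial.
#' @param base_amp CS- amplitude, constant over trials.
#' @param sep_start,sep_end Pattern-separation coefficient (in `[0, 1]`) at
#'   the first and last trial; 0 means CS+ and CS- share one voxel pattern,
#'   1 means fully condition-specific patterns.
#' @param noise_sd BOLD white-noise SD (same units as the amplitudes).
#' @param drift_order,drift_sd Order and coefficient SD of the per-voxel
#'   polynomial scanner drift.
#' @param us_amplitude Amplitude of the US-evoked response on paired trials.
#' @param hr_csplus_bpm,hr_csminus_bpm Peak heart-rate deceleration
#'   (beats/min) after CS+ and CS- onsets.
#' @param hr_latency_s,hr_width_s Latency and Gaussian width of the
#'   deceleration bump (s after CS onset).
#' @param hr_decays Logical; if `TRUE` the CS+/CS- deceleration difference is
#'   modulated over trials by the same normalised curve as the BOLD
#'   difference.
#' @param hr_noise_bpm SD of the heart-rate noise (beats/min).
#' @param seed Seed used when the truth itself needs randomness (voxel
#'   patterns are drawn at simulation time from this seed).
#' @return A list of class `fc_truth`.
#' @export
planted_truth <- function(n_trials = 120L,
                          change_point = 60L,
                          early_diff = 1,
                          late_diff = 0,
                          base_amp = 1,
                          sep_start = 0.8,
                          sep_end = 0.1,
                          noise_sd = 0.5,
                          drift_order = 2L,
                          drift_sd = 0,
                          us_amplitude = 2,
                          hr_csplus_bpm = 5,
                          hr_csminus_bpm = 1,
                          hr_latency_s = 2.5,
                          hr_width_s = 1,
                          hr_decays = TRUE,
                          hr_noise_bpm = 0,
                          seed = 1L) {
  stopifnot(n_trials >= 1, noise_sd >= 0, change_point >= 1,
            change_point <= n_trials, sep_start >= 0, sep_start <= 1,
            sep_end >= 0, sep_end <= 1)
  idx <- seq_len(n_trials)
  diff_curve <- rep(early_diff, n_trials)
  if (change_point < n_trials) {
    tail_idx <- idx[idx > change_point]
    diff_curve[tail_idx] <- early_diff +
      (late_diff - early_diff) * (tail_idx - change_point) / (n_trials - change_point)
  }
  denom <- max(abs(diff_curve), 1e-12)
  new_truth(
    n_trials = as.integer(n_trials),
    amp_csplus = base_amp + diff_curve,
    amp_csminus = rep(base_amp, n_trials),
    change_point = as.integer(change_point),
    separation = sep_start + (sep_end - sep_start) * (idx - 1) / max(n_trials - 1, 1),
    noise_sd = noise_sd,
    drift_order = as.integer(drift_order),
    drift_sd = drift_sd,
    us_amplitude = us_amplitude,
    hr = list(
      CSplus = list(amplitude_bpm = hr_csplus_bpm, latency_s = hr_latency_s,
                    width_s = hr_width_s),
      CSminus = list(amplitude_bpm = hr_csminus_bpm, latency_s = hr_latency_s,
                     width_s = hr_width_s)
    ),
    hr_mod = if (hr_decays) diff_curve / denom else rep(1, n_trials),
    hr_noise_bpm = hr_noise_bpm,
    seed = as.integer(seed)
  )
}

#' @rdname planted_truth
#' @param separation Constant pattern-separation coefficient for the null
#'   truth.
#' @export
null_truth <- function(n_trials = 120L,
                       base_amp = 1,
                       separation = 0.5,
                       noise_sd = 0.5,
                       drift_order = 2L,
                       drift_sd = 0,
                       us_amplitude = 2,
                       hr_csplus_bpm = 0,
                       hr_csminus_bpm = 0,
                       hr_latency_s = 2.5,
                       hr_width_s = 1,
                       hr_noise_bpm = 0,
                       seed = 1L) {
  new_truth(
    n_trials = as.integer(n_trials),
    amp_csplus = rep(base_amp, n_trials),
    amp_csminus = rep(base_amp, n_trials),
    change_point = NA_integer_,
    separation = rep(separation, n_trials),
    noise_sd = noise_sd,
    drift_order = as.integer(drift_order),
    drift_sd = drift_sd,
    us_amplitude = us_amplitude,
    hr = list(
      CSplus = list(amplitude_bpm = hr_csplus_bpm, latency_s = hr_latency_s,
                    width_s = hr_width_s),
      CSminus = list(amplitude_bpm = hr_csminus_bpm, latency_s = hr_latency_s,
                     width_s = hr_width_s)
    ),
    hr_mod = rep(1, n_trials),
    hr_noise_bpm = hr_noise_bpm,
    seed = as.integer(seed)
  )
}

new_truth <- function(...) {
  x <- list(...)
  stopifnot(x$noise_sd >= 0,
            length(x$amp_csplus) == x$n_trials,
            length(x$amp_csminus) == x$n_trials,
            length(x$separation) == x$n_trials,
            all(x$separation >= 0 & x$separation <= 1))
  structure(x, class = "fc_truth")
}

#' @export
print.fc_truth <- function(x, ...) {
  cat(sprintf("<fc_truth> %d trials, change point %s, noise sd %.3g\n",
              x$n_trials,
              if (is.na(x$change_point)) "none" else x$change_point,
              x$noise_sd))
  cat(sprintf("  amplitude diff %.3g -> %.3g; separation %.2f -> %.2f\n",
              x$amp_csplus[1] - x$amp_csminus[1],
              x$amp_csplus[x$n_trials] - x$amp_csminus[x$n_trials],
              x$separation[1], x$separation[x$n_trials]))
  invisible(x)
}

# per-trial amplitude for the condition actually shown on each trial
truth_trial_amplitudes <- function(truth, design) {
  n <- nrow(design)
  if (truth$n_trials < n) stop("truth describes fewer trials than the design")
  ifelse(cs_condition(design) == "CSplus",
         truth$amp_csplus[seq_len(n)], truth$amp_csminus[seq_len(n)])
}
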