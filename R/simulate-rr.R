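#' Simulate an RR-interval series with stimulus-locked decelerations
#'
#' Builds an instantaneous heart-rate function: a constant baseline minus a
#' negative Gaussian "orienting" bump after each CS onset (amplitude, latency
#' and width per condition from the truth, optionally modulated over trials),
#' plus piecewise-constant white rate noise on 1-s knots. Beats are obtained
#' by integrating the rate: each inter-beat (RR) interval is the time the
#' integrated rate takes to accumulate one beat.
#'
#' @param design An `fc_design`.
#' @param truth An `fc_truth`; uses its `hr`, `hr_mod` and `hr_noise_bpm`
#'   fields.
#' @param baseline_bpm Baseline heart rate (beats/min), > 0.
#' @param duration_s Recording length (s); default covers the design plus
#'   10 s.
#' @param seed Seed for the rate noise.
#' @param dt_s Integration step (s).
#' @return An object of class `rr_series`: `intervals` (s), `beat_times`
#'   (s, first beat after time 0), `duration_s`.
#' @export
simulate_rr <- function(design, truth, baseline_bpm = 70, duration_s = NULL,
                        seed = truth$seed, dt_s = 0.005) {
  if (baseline_bpm <= 0) stop("'baseline_bpm' must be positive")
  amps <- c(truth$hr$CSplus$amplitude_bpm, truth$hr$CSminus$amplitude_bpm)
  if (max(abs(amps) * max(abs(truth$hr_mod))) >= baseline_bpm) {
    stop("deceleration amplitude >= baseline: heart rate would be non-positive")
  }
  if (is.null(duration_s)) duration_s <- attr(design, "total_duration_s") + 10

  tt <- seq(0, duration_s, by = dt_s)
  rate <- rep(baseline_bpm, length(tt))
  cond <- cs_condition(design)
  for (i in seq_len(nrow(design))) {
    p <- truth$hr[[if (cond[i] == "CSplus") "CSplus" else "CSminus"]]
    a <- p$amplitude_bpm * truth$hr_mod[i]
    if (a == 0) next
    mu <- design$onset[i] + p$latency_s
    # evaluate the bump only on its +-5 sd support
    lo <- max(1L, floor((mu - 5 * p$width_s) / dt_s) + 1L)
    hi <- min(length(tt), ceiling((mu + 5 * p$width_s) / dt_s) + 1L)
    idx <- lo:hi
    rate[idx] <- rate[idx] - a * exp(-(tt[idx] - mu)^2 / (2 * p$width_s^2))
  }
  if (truth$hr_noise_bpm > 0) {
    set.seed(as.integer(seed))
    knots <- stats::rnorm(ceiling(duration_s) + 1L, sd = truth$hr_noise_bpm)
    rate <- rate + knots[floor(tt) + 1L]
  }
  if (any(rate <= 0)) stop("simulated heart rate is non-positive")

  # cumulative beats; left-Riemann integral of rate/60
  beats <- cumsum(c(0, rate[-length(rate)] / 60 * dt_s))
  n_beats <- floor(beats[length(beats)])
  if (n_beats < 2L) stop("recording too short: fewer than 2 beats")
  beat_times <- stats::approx(beats, tt, xout = seq_len(n_beats), ties = "ordered")$y
  intervals <- diff(c(0, beat_times))
  structure(list(intervals = intervals, beat_times = beat_times,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s (mean RR %.3f s)\n",
              length(x$intervals), x$duration_s, mean(x$intervals)))
  invisible(x)
}

#' Write / read RR intervals as plain text
#'
#' One interval per line, seconds.
#'
#' @param rr An `rr_series` or numeric vector of intervals.
#' @param path File path.
#' @return `write_rr` returns `path` invisibly; `read_rr` returns an
#'   `rr_series`.
#' @export
write_rr <- function(rr, path) {
  intervals <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  writeLines(sprintf("%.6f", intervals), path)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  intervals <- as.numeric(readLines(path))
  if (anyNA(intervals)) stop("non-numeric RR interval in ", path)
  beat_times <- cumsum(intervals)
  structure(list(intervals = intervals, beat_times = beat_times,
                 duration_s = beat_times[length(beat_times)], seed = NA_integer_),
            class = "rr_series")
}
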