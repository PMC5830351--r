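#' Canonical double-gamma hemodynamic response function
#'
#' The standard impulse response linking a brief neural event to the BOLD
#' signal: a gamma density peaking around 5 s minus a later, smaller gamma
#' density modelling the post-stimulus undershoot. Parameters follow the
#' common convention (response delay 6 s, undershoot delay 16 s, unit
#' dispersions, undershoot ratio 1/6, 32-s support); the curve is normalised
#' to a peak of 1 and is identically zero outside `[0, length_s]`.
#'
#' @param t_grid_s Non-negative, strictly increasing time grid (s).
#' @param params Optional list overriding any of `peak_delay`, `under_delay`,
#'   `peak_disp`, `under_disp`, `ratio`, `length_s`.
#' @return Numeric vector of responses on `t_grid_s`.
#' @examples
#' canonical_hrf(0)            # 0 at onset
#' t <- seq(0, 32, by = 0.1)
#' t[which.max(canonical_hrf(t))]  # ~5 s
#' @export
canonical_hrf <- function(t_grid_s, params = list()) {
  p <- utils::modifyList(hrf_default_params(), params)
  if (any(t_grid_s < 0)) stop("'t_grid_s' must be non-negative")
  if (length(t_grid_s) > 1 && any(diff(t_grid_s) <= 0)) {
    stop("'t_grid_s' must be strictly increasing")
  }
  h <- hrf_raw(t_grid_s, p)
  h / hrf_peak_value(p)
}

hrf_default_params <- function() {
  list(peak_delay = 6, under_delay = 16, peak_disp = 1, under_disp = 1,
       ratio = 1 / 6, length_s = 32)
}

hrf_raw <- function(t, p) {
  out <- stats::dgamma(t, shape = p$peak_delay / p$peak_disp,
                       rate = 1 / p$peak_disp) -
    p$ratio * stats::dgamma(t, shape = p$under_delay / p$under_disp,
                            rate = 1 / p$under_disp)
  out[t > p$length_s] <- 0
  out
}

# peak on a dense grid so normalisation is independent of the caller's grid
hrf_peak_value <- function(p) {
  tt <- seq(0, p$length_s, by = 0.001)
  max(hrf_raw(tt, p))
}

# Event regressors sampled at scan times. Each event is a boxcar convolved
# with the canonical HRF on a fine grid (tr_s/oversample), then normalised so
# that a unit-amplitude event of that duration has regressor peak 1: a beta
# of b means a peak evoked response of b signal units.
event_regressors <- function(onsets, durations, tr_s, n_scans,
                             hrf_params = list(), oversample = 20L) {
  p <- utils::modifyList(hrf_default_params(), hrf_params)
  dt <- tr_s / oversample
  n_fine <- ceiling((n_scans * tr_s + p$length_s) / dt) + 1L
  hrf_fine <- canonical_hrf(seq(0, p$length_s, by = dt), hrf_params)

  # one convolution kernel per unique duration, peak-normalised
  kernels <- lapply(unique(durations), function(d) {
    nbox <- max(1L, round(d / dt))
    k <- stats::filter(c(hrf_fine, numeric(nbox)), rep(1, nbox),
                       sides = 1, method = "convolution")
    k[is.na(k)] <- 0
    as.numeric(k / max(k))
  })
  names(kernels) <- as.character(unique(durations))

  X <- matrix(0, nrow = n_scans, ncol = length(onsets))
  scan_idx <- round((seq_len(n_scans) - 1L) * tr_s / dt) + 1L
  for (j in seq_along(onsets)) {
    k <- kernels[[as.character(durations[j])]]
    col <- numeric(n_fine)
    i0 <- round(onsets[j] / dt) + 1L
    span <- i0:min(n_fine, i0 + length(k) - 1L)
    col[span] <- k[seq_along(span)]
    X[, j] <- col[scan_idx]
  }
  X
}
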