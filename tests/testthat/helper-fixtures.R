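# shared fixtures: small noiseless simulations and hand-built containers

quiet_truth <- function(n_trials = 120L, ...) {
  planted_truth(n_trials = n_trials, noise_sd = 0, drift_sd = 0,
                hr_noise_bpm = 0, ...)
}

# beta series built directly (no GLM), for units that only need the container:
# alternating CS+/CS- trials, ~5.6 s apart, optional paired trials
make_beta_series <- function(n_trials = 120L, n_voxels = 6L,
                             betas = NULL, values = NULL,
                             spacing_s = 5.6) {
  condition <- rep(c("CSplus_unpaired", "CSminus"), length.out = n_trials)
  onset <- spacing_s * seq_len(n_trials)
  trials <- data.frame(trial = seq_len(n_trials), onset = onset,
                       duration = 1, condition = condition,
                       us_onset = NA_real_, stringsAsFactors = FALSE)
  if (is.null(betas)) {
    if (is.null(values)) values <- rep(0, n_trials)
    betas <- matrix(rep(values, n_voxels), n_trials, n_voxels)
  }
  structure(list(betas = betas, trials = trials, resid_var = NULL,
                 subject = "sub-01", roi = "test", tr_s = 1.98,
                 options = list()),
            class = "beta_series")
}

# trial-series data.frame for the univariate dynamics functions
make_trial_series <- function(values_plus, values_minus, spacing_s = 5.6) {
  n <- length(values_plus) + length(values_minus)
  onset <- spacing_s * seq_len(n)
  condition <- rep(c("CSplus", "CSminus"), length.out = n)
  value <- numeric(n)
  value[condition == "CSplus"] <- values_plus
  value[condition == "CSminus"] <- values_minus
  data.frame(trial = seq_len(n), onset = onset, condition = condition,
             value = value, stringsAsFactors = FALSE)
}

# piecewise-constant instantaneous-rate object built directly
make_inst_hr <- function(breaks, rates) {
  structure(list(breaks = breaks, rates = rates,
                 duration_s = breaks[length(breaks)],
                 interpolated = integer(0)),
            class = "inst_hr")
}
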