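#' Simulate ROI BOLD data from a design and ground truth
#'
#' Forward model for the single-trial GLM: every trial contributes its planted
#' amplitude times a voxel pattern times the HRF-convolved boxcar at its
#' onset. The trial-`t` pattern is `(1 - c_t) * shared + c_t * condition`,
#' where `c_t` is the truth's separation coefficient, the shared and
#' condition-specific patterns have unit mean, and the two condition-specific
#' heterogeneity components are exactly orthogonal (so full separation yields
#' zero pattern correlation). Paired trials additionally contribute a
#' US-evoked response with its own pattern. A per-voxel polynomial drift,
#' white noise, and a constant baseline are added on top.
#'
#' Because the signal is built from the same regressors the GLM fits, the
#' noiseless beta series reproduces the planted trial-by-voxel amplitudes to
#' machine precision (on the unscaled path).
#'
#' @param design An `fc_design`.
#' @param truth An `fc_truth` (see [planted_truth()]).
#' @param n_voxels Number of voxels (>= 2).
#' @param tr_s Repetition time (s).
#' @param n_scans Number of scans; must cover the design plus a 20-s HRF
#'   tail. Default: the smallest such number.
#' @param baseline Constant signal baseline added to every voxel.
#' @param pattern_cv SD of the voxel-pattern heterogeneity around its unit
#'   mean.
#' @param seed Seed for patterns, drift and noise (default: the truth's).
#' @param hrf_params HRF parameter overrides.
#' @return An object of class `roi_sim`: `data` (voxel x scan), `tr_s`,
#'   `design`, `truth_betas` (the planted trial x voxel amplitudes the GLM
#'   should recover), `patterns`, and the simulation settings.
#' @export
simulate_bold_roi <- function(design, truth, n_voxels = 30L, tr_s = 1.98,
                              n_scans = NULL, baseline = 100,
                              pattern_cv = 0.5, seed = truth$seed,
                              hrf_params = list()) {
  if (n_voxels < 2L) stop("'n_voxels' must be >= 2 (pattern analyses undefined)")
  total <- attr(design, "total_duration_s")
  if (is.null(n_scans)) n_scans <- ceiling((total + 20) / tr_s)
  if (n_scans * tr_s < total + 20) {
    stop("'n_scans' too small: run must cover the design plus a 20-s tail")
  }
  n_trials <- nrow(design)

  set.seed(as.integer(seed))
  z_shared <- centered_unit(stats::rnorm(n_voxels))
  z_plus <- orthogonalize(stats::rnorm(n_voxels), cbind(1, z_shared))
  z_minus <- orthogonalize(stats::rnorm(n_voxels), cbind(1, z_shared, z_plus))
  z_us <- orthogonalize(stats::rnorm(n_voxels), cbind(1, z_shared))
  p_shared <- 1 + pattern_cv * z_shared
  p_plus <- 1 + pattern_cv * z_plus
  p_minus <- 1 + pattern_cv * z_minus
  p_us <- 1 + pattern_cv * z_us

  amp <- truth_trial_amplitudes(truth, design)
  cc <- truth$separation[seq_len(n_trials)]
  is_plus <- cs_condition(design) == "CSplus"
  # trial x voxel planted amplitudes
  V <- outer(1 - cc, p_shared) +
    cc * (outer(as.numeric(is_plus), p_plus) + outer(as.numeric(!is_plus), p_minus))
  truth_betas <- amp * V

  S <- event_regressors(design$onset, design$duration, tr_s, n_scans,
                        hrf_params = hrf_params)
  signal <- t(S %*% truth_betas)  # voxel x scan

  us_on <- design$us_onset[!is.na(design$us_onset)]
  if (length(us_on) && truth$us_amplitude != 0) {
    U <- event_regressors(us_on, rep(1, length(us_on)), tr_s, n_scans,
                          hrf_params = hrf_params)
    signal <- signal + truth$us_amplitude * outer(p_us, rowSums(U))
  }

  if (truth$drift_sd > 0 && truth$drift_order > 0L) {
    tt <- seq(-1, 1, length.out = n_scans)
    P <- vapply(seq_len(truth$drift_order), function(k) tt^k, numeric(n_scans))
    C <- matrix(stats::rnorm(n_voxels * truth$drift_order, sd = truth$drift_sd),
                n_voxels, truth$drift_order)
    signal <- signal + tcrossprod(C, P)
  }
  if (truth$noise_sd > 0) {
    signal <- signal + matrix(stats::rnorm(length(signal), sd = truth$noise_sd),
                              nrow(signal), ncol(signal))
  }
  data <- signal + baseline

  structure(list(data = data, tr_s = tr_s, design = design,
                 truth_betas = truth_betas,
                 patterns = list(shared = p_shared, csplus = p_plus,
                                 csminus = p_minus, us = p_us),
                 n_scans = n_scans, baseline = baseline,
                 pattern_cv = pattern_cv, seed = as.integer(seed)),
            class = "roi_sim")
}

centered_unit <- function(z) {
  z <- z - mean(z)
  z / stats::sd(z)
}

# residual of z on the columns of M, rescaled to unit sd; with too few
# voxels to residualise, fall back to a centred draw (patterns then only
# approximately orthogonal)
orthogonalize <- function(z, M) {
  if (length(z) <= ncol(M) + 1L) return(centered_unit(z))
  r <- stats::lm.fit(M, z)$residuals
  if (stats::sd(r) == 0) return(centered_unit(z))
  r / stats::sd(r)
}

#' @export
print.roi_sim <- function(x, ...) {
  cat(sprintf("<roi_sim> %d voxels x %d scans (TR %.3f s), %d trials\n",
              nrow(x$data), ncol(x$data), x$tr_s, nrow(x$design)))
  invisible(x)
}

#' Convert a simulated ROI to a `roi_timeseries`
#'
#' @param sim An `roi_sim`.
#' @param nuisance Optional scan x k nuisance matrix.
#' @param roi,subject Identifiers to attach.
#' @return A [roi_timeseries()].
#' @export
as_roi_timeseries <- function(sim, nuisance = NULL,
                              roi = "roi", subject = "sub-01") {
  roi_timeseries(sim$data, sim$tr_s, nuisance = nuisance,
                 roi = roi, subject = subject)
}

#' Write / read an ROI matrix as delimited text plus JSON sidecar
#'
#' Voxel x scan matrix, tab-separated, no header; the sidecar records
#' `{tr_s, n_voxels}`.
#'
#' @param data Voxel x scan matrix (or an `roi_sim`).
#' @param tr_s Repetition time (s); taken from an `roi_sim` automatically.
#' @param path TSV path; sidecar written next to it as `.json`.
#' @return `write_roi_matrix` returns `path` invisibly; `read_roi_matrix`
#'   returns a list `(data, tr_s, n_voxels)`.
#' @export
write_roi_matrix <- function(data, path, tr_s = NULL) {
  if (inherits(data, "roi_sim")) {
    tr_s <- data$tr_s
    data <- data$data
  }
  if (is.null(tr_s)) stop("'tr_s' must be supplied for a bare matrix")
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tr_s = tr_s, n_voxels = nrow(data)),
                       sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_matrix
#' @export
read_roi_matrix <- function(path) {
  data <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  list(data = data, tr_s = meta$tr_s %||% NA_real_, n_voxels = nrow(data))
}
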