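#' Region-of-interest BOLD time series
#'
#' Thin container for a voxel-by-scan matrix plus its repetition time and
#' optional nuisance regressors (e.g., the six rigid-body motion parameters).
#'
#' @param data Numeric voxel x scan matrix, no missing values.
#' @param tr_s Repetition time (s), > 0.
#' @param nuisance Optional scan x k matrix of nuisance regressors.
#' @param roi,subject Identifier strings carried into downstream outputs.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_s, nuisance = NULL,
                           roi = "roi", subject = "sub-01") {
  data <- as.matrix(data)
  if (anyNA(data)) stop("BOLD matrix contains missing values")
  if (ncol(data) < 2L) stop("need at least 2 scans")
  if (tr_s <= 0) stop("'tr_s' must be positive")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != ncol(data)) {
      stop("nuisance matrix must have one row per scan")
    }
  }
  structure(list(data = data, tr_s = tr_s, nuisance = nuisance,
                 roi = roi, subject = subject),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s / %s: %d voxels x %d scans, TR %.3f s\n",
              x$subject, x$roi, nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

#' Grand-mean (global) scaling of a BOLD matrix
#'
#' Divides every scan by its spatial mean and multiplies by 100, so each
#' scan's spatial mean is exactly 100. Removes the global signal; the
#' operation is idempotent and invariant to overall gain.
#'
#' @param data Voxel x scan matrix with strictly positive scan means.
#' @return Scaled matrix of the same dimensions.
#' @export
global_scale <- function(data) {
  data <- as.matrix(data)
  m <- colMeans(data)
  if (any(m <= 0)) stop("global scaling undefined: non-positive scan mean(s)")
  sweep(data, 2L, m, "/") * 100
}

#' Discrete-cosine high-pass basis
#'
#' Cosine regressors spanning all periods at or above `cutoff_s`, excluding
#' the constant term (absorbed by the GLM intercept). Columns are zero-sum,
#' so regressing them out leaves per-voxel means unchanged.
#'
#' @param n_scans Number of scans.
#' @param tr_s Repetition time (s).
#' @param cutoff_s Slowest period to remove (s); default 128.
#' @return `n_scans` x K matrix (K may be 0 for short records).
#' @export
dct_basis <- function(n_scans, tr_s, cutoff_s = 128) {
  K <- floor(2 * n_scans * tr_s / cutoff_s)
  K <- min(K, n_scans - 1L)
  if (K < 1L) return(matrix(0, n_scans, 0))
  s <- seq_len(n_scans) - 1L
  vapply(seq_len(K),
         function(k) cos(pi * (2 * s + 1) * k / (2 * n_scans)),
         numeric(n_scans))
}

#' Temporal high-pass filter
#'
#' Removes slow drifts by regressing each voxel's time series on the
#' discrete-cosine basis of [dct_basis()] and keeping the residual; the
#' per-voxel mean is preserved exactly. If the record is shorter than one
#' cutoff period the filter is skipped with a warning.
#'
#' @param data Voxel x scan matrix.
#' @param tr_s Repetition time (s).
#' @param cutoff_s Cutoff period (s); frequencies below `1/cutoff_s` Hz are
#'   removed. Must exceed `2 * tr_s`.
#' @return Filtered matrix of the same dimensions.
#' @export
high_pass <- function(data, tr_s, cutoff_s = 128) {
  data <- as.matrix(data)
  if (cutoff_s <= 2 * tr_s) stop("'cutoff_s' must exceed 2 * tr_s")
  n <- ncol(data)
  if (n * tr_s < cutoff_s) {
    warning("record shorter than the cutoff period; high-pass filter skipped")
    return(data)
  }
  B <- dct_basis(n, tr_s, cutoff_s)
  if (ncol(B) == 0L) return(data)
  # DCT columns are mutually orthogonal: projection is B (B'B)^-1 B'
  coef <- (data %*% B) %*% diag(1 / colSums(B^2), ncol(B))
  data - tcrossprod(coef, B)
}

#' Build the single-trial GLM design matrix
#'
#' One regressor per CS trial (boxcar of the trial's duration at its onset,
#' convolved with the canonical HRF, sampled at scan times), optionally one
#' regressor per US event, followed by any nuisance columns and a trailing
#' intercept. Column labels identify each trial's index and condition.
#'
#' @param design An `fc_design` (or compatible data.frame with `onset`,
#'   `duration`, `condition`, `us_onset`).
#' @param tr_s Repetition time (s).
#' @param n_scans Number of scans; all onsets must fall before
#'   `n_scans * tr_s`.
#' @param nuisance Optional scan x k nuisance matrix.
#' @param include_us_regressors Model US events as separate regressors?
#' @param us_duration_s US boxcar duration (s).
#' @param hrf_params Optional HRF parameter overrides (see [canonical_hrf()]).
#' @return A list of class `fc_design_matrix` with elements `X` (scan x p
#'   matrix), `labels`, and the column index vectors `trial_cols`, `us_cols`,
#'   `nuisance_cols`, `intercept_col`.
#' @export
build_design_matrix <- function(design, tr_s, n_scans, nuisance = NULL,
                                include_us_regressors = TRUE,
                                us_duration_s = 1,
                                hrf_params = list()) {
  if (any(design$onset >= n_scans * tr_s)) {
    stop("trial onsets extend beyond the scanning run")
  }
  if (any(diff(sort(design$onset)) < tr_s / 2)) {
    warning("some trial onsets are closer than tr_s/2: regressors may be collinear")
  }
  Xt <- event_regressors(design$onset, design$duration, tr_s, n_scans,
                         hrf_params = hrf_params)
  labels <- sprintf("trial_%03d_%s", design$trial, design$condition)

  us_cols <- integer(0)
  if (include_us_regressors) {
    us_on <- design$us_onset[!is.na(design$us_onset)]
    if (length(us_on)) {
      Xu <- event_regressors(us_on, rep(us_duration_s, length(us_on)),
                             tr_s, n_scans, hrf_params = hrf_params)
      us_cols <- ncol(Xt) + seq_len(ncol(Xu))
      labels <- c(labels, sprintf("us_%03d", design$trial[!is.na(design$us_onset)]))
      Xt <- cbind(Xt, Xu)
    }
  }

  nuisance_cols <- integer(0)
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0L) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance matrix must have n_scans rows")
    nuisance_cols <- ncol(Xt) + seq_len(ncol(nuisance))
    labels <- c(labels, sprintf("nuisance_%d", seq_len(ncol(nuisance))))
    Xt <- cbind(Xt, nuisance)
  }

  X <- cbind(Xt, 1)
  labels <- c(labels, "intercept")
  colnames(X) <- labels

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- labels[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, labels = labels,
                 trial_cols = seq_len(nrow(design)),
                 us_cols = us_cols,
                 nuisance_cols = nuisance_cols,
                 intercept_col = ncol(X)),
            class = "fc_design_matrix")
}

#' Estimate a single-trial beta series
#'
#' Fits, per voxel, an ordinary-least-squares GLM in which every CS trial has
#' its own HRF-convolved regressor, and returns the trial coefficients: one
#' beta per trial per voxel. By default the data are grand-mean scaled
#' ([global_scale()]) and high-pass filtered ([high_pass()]); the same
#' discrete-cosine basis used by the filter is appended to the design matrix
#' as confound columns so data and regressors are treated consistently.
#'
#' @param roi A [roi_timeseries()].
#' @param design An `fc_design`.
#' @param options List of options: `global_scale` (default `TRUE`),
#'   `high_pass` (default `TRUE`), `cutoff_s` (128), `include_us_regressors`
#'   (`TRUE`), `us_duration_s` (1), `hrf_params` (list()), `ridge` (0; >0
#'   adds a ridge penalty on all columns except the intercept),
#'   `condition_warn` (1e8; warn if the design condition number exceeds it).
#' @return An object of class `beta_series`: `betas` (trial x voxel matrix),
#'   `trials` (the design rows), `resid_var` (per-voxel residual variance),
#'   plus subject/roi ids and the options used.
#' @export
estimate_beta_series <- function(roi, design, options = list()) {
  opt <- utils::modifyList(list(global_scale = TRUE, high_pass = TRUE,
                                cutoff_s = 128, include_us_regressors = TRUE,
                                us_duration_s = 1, hrf_params = list(),
                                ridge = 0, condition_warn = 1e8),
                           options)
  Y <- roi$data
  n_scans <- ncol(Y)
  if (opt$global_scale) Y <- global_scale(Y)
  dm <- build_design_matrix(design, roi$tr_s, n_scans,
                            nuisance = roi$nuisance,
                            include_us_regressors = opt$include_us_regressors,
                            us_duration_s = opt$us_duration_s,
                            hrf_params = opt$hrf_params)
  X <- dm$X
  if (opt$high_pass && n_scans * roi$tr_s >= opt$cutoff_s) {
    Y <- high_pass(Y, roi$tr_s, opt$cutoff_s)
    B <- dct_basis(n_scans, roi$tr_s, opt$cutoff_s)
    if (ncol(B) > 0L) {
      colnames(B) <- sprintf("dct_%d", seq_len(ncol(B)))
      X <- cbind(X, B)
    }
  } else if (opt$high_pass) {
    warning("record shorter than the cutoff period; high-pass filter skipped")
  }

  kap <- kappa(X, exact = FALSE)
  if (kap > opt$condition_warn) {
    warning(sprintf("design matrix condition number %.3g exceeds %.3g",
                    kap, opt$condition_warn))
  }

  if (opt$ridge > 0) {
    pen <- rep(opt$ridge, ncol(X))
    pen[dm$intercept_col] <- 0
    XtX <- crossprod(X) + diag(pen)
    coefs <- solve(XtX, crossprod(X, t(Y)))
    rank <- ncol(X)
  } else {
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("design matrix is rank deficient after filtering")
    coefs <- qr.coef(qx, t(Y))
    rank <- qx$rank
  }
  fitted <- X %*% coefs
  rdf <- max(n_scans - rank, 1L)
  resid_var <- colSums((t(Y) - fitted)^2) / rdf

  betas <- coefs[dm$trial_cols, , drop = FALSE]  # trial x voxel
  dimnames(betas) <- list(dm$labels[dm$trial_cols],
                          paste0("v", seq_len(nrow(roi$data))))
  structure(list(betas = betas,
                 trials = as.data.frame(design),
                 resid_var = unname(resid_var),
                 subject = roi$subject,
                 roi = roi$roi,
                 tr_s = roi$tr_s,
                 options = opt),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series> %s / %s: %d trials x %d voxels\n",
              x$subject, x$roi, nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Write / read a beta series as TSV plus JSON sidecar
#'
#' The TSV has one row per trial (`trial_index`, `onset`, `condition`, then
#' one column per voxel); the sidecar records subject, roi, TR and the
#' estimation options.
#'
#' @param beta A `beta_series`.
#' @param path TSV path; the sidecar is written next to it as `.json`.
#' @return `write_beta_series` returns `path` invisibly; `read_beta_series`
#'   returns a `beta_series` (residual variances are not round-tripped).
#' @export
write_beta_series <- function(beta, path) {
  df <- data.frame(trial_index = beta$trials$trial,
                   onset = beta$trials$onset,
                   condition = beta$trials$condition,
                   beta$betas,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  opts <- beta$options
  opts$hrf_params <- NULL
  jsonlite::write_json(list(subject = beta$subject, roi = beta$roi,
                            tr_s = beta$tr_s, options = opts),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beta_series
#' @export
read_beta_series <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  voxel_cols <- setdiff(names(df), c("trial_index", "onset", "condition"))
  trials <- data.frame(trial = df$trial_index, onset = df$onset,
                       duration = NA_real_, condition = df$condition,
                       us_onset = NA_real_, stringsAsFactors = FALSE)
  structure(list(betas = as.matrix(df[, voxel_cols, drop = FALSE]),
                 trials = trials,
                 resid_var = NULL,
                 subject = meta$subject %||% "unknown",
                 roi = meta$roi %||% "unknown",
                 tr_s = meta$tr_s %||% NA_real_,
                 options = meta$options %||% list()),
            class = "beta_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
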