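#' Configuration for a full synthetic-study run
#'
#' Assembles the parameters of every stage with defaults matching the study
#' paradigm: 18 subjects, three salience-network ROIs, 120-trial blocks with
#' 25% reinforcement after four always-paired CS+ trials, TR 1.98 s, ITI
#' 4.6 +/- 1.5 s, 128-s high-pass, 5-trial smoothing bandwidth, 1000
#' permutations at a 95% threshold, 50-trial RSA windows stepping by 2, and
#' -1..5-s heart-rate bins.
#'
#' @param n_subjects Number of simulated subjects.
#' @param rois ROI names; the first is treated as the univariate adaptation
#'   reference (amygdala role), the remainder as the pattern-analysis ROIs.
#' @param truth_type `"planted"` (acquisition-style effects) or `"null"`
#'   (habituation-style, no condition differences).
#' @param truth_args Extra arguments passed to [planted_truth()] or
#'   [null_truth()].
#' @param n_trials,pairing_rate,n_initial_paired,iti_mean_s,iti_sd_s Design
#'   parameters (see [generate_design()]).
#' @param tr_s Repetition time (s).
#' @param n_voxels Voxels per ROI.
#' @param glm_options Options for [estimate_beta_series()]. The pipeline
#'   default turns per-scan global scaling off: in an ROI-only simulation
#'   there is no surrounding brain, so the scan's spatial mean is dominated
#'   by the planted signal itself and proportional scaling would remove it.
#'   With real whole-brain-derived data pass
#'   `glm_options = list(global_scale = TRUE)`.
#' @param bandwidth_trials Gaussian smoother SD (trials).
#' @param t_split_s Early/late demarcation (s).
#' @param n_permutations,cp_threshold Change-point permutation settings.
#' @param rsa_window,rsa_step,endpoint_k RSA settings.
#' @param hr_baseline_bpm,hr_window,hr_bin_s,hr_decel_window Heart-rate
#'   settings.
#' @param seed Root seed; every per-subject and per-stage stream is derived
#'   from it.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(n_subjects = 18L,
                            rois = c("amygdala", "insula", "dACC"),
                            truth_type = c("planted", "null"),
                            truth_args = list(),
                            n_trials = 120L,
                            pairing_rate = 0.25,
                            n_initial_paired = 4L,
                            iti_mean_s = 4.6,
                            iti_sd_s = 1.5,
                            tr_s = 1.98,
                            n_voxels = 30L,
                            glm_options = list(global_scale = FALSE),
                            bandwidth_trials = 5,
                            t_split_s = 336,
                            n_permutations = 1000L,
                            cp_threshold = 95,
                            rsa_window = 50L,
                            rsa_step = 2L,
                            endpoint_k = 10L,
                            hr_baseline_bpm = 70,
                            hr_window = c(-1, 5),
                            hr_bin_s = 1,
                            hr_decel_window = c(1, 4),
                            seed = 1L) {
  structure(list(n_subjects = as.integer(n_subjects), rois = rois,
                 truth_type = match.arg(truth_type), truth_args = truth_args,
                 n_trials = as.integer(n_trials), pairing_rate = pairing_rate,
                 n_initial_paired = as.integer(n_initial_paired),
                 iti_mean_s = iti_mean_s, iti_sd_s = iti_sd_s,
                 tr_s = tr_s, n_voxels = as.integer(n_voxels),
                 glm_options = glm_options,
                 bandwidth_trials = bandwidth_trials, t_split_s = t_split_s,
                 n_permutations = as.integer(n_permutations),
                 cp_threshold = cp_threshold,
                 rsa_window = as.integer(rsa_window),
                 rsa_step = as.integer(rsa_step),
                 endpoint_k = as.integer(endpoint_k),
                 hr_baseline_bpm = hr_baseline_bpm, hr_window = hr_window,
                 hr_bin_s = hr_bin_s, hr_decel_window = hr_decel_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

# deterministic per-subject / per-stage seed stream, kept below 2^31
derive_seed <- function(root, subject, stage) {
  (as.double(root) * 7919 + subject * 104729 + stage * 15485863) %% 2147483647
}

#' Run the full analysis pipeline on synthetic data
#'
#' For each subject: generates a design, simulates ROI BOLD and RR data from
#' the configured truth, estimates beta series, computes early/late
#' differentials, smoothed differential curves and per-subject change
#' points, sliding-window dissimilarity curves and their slopes, and
#' heart-rate dynamics. At the group level: early/late paired tests with
#' FDR correction (BOLD ROIs plus heart rate), change-point detection on
#' the group-mean contrast series, change-point concordance (ANOVA, PCA,
#' PC1 vs heart-rate difference), group dissimilarity curves with endpoint
#' tests, and slope concordance against the reference ROI's adaptation
#' slope. Any stage failure raises an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `fc_report` with sections `early_late`,
#'   `change_points`, `concordance`, `rsa`, `hr`, `slopes`, plus the config.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rois <- config$rois
  n_sub <- config$n_subjects
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  make_truth <- function(s) {
    args <- utils::modifyList(list(n_trials = config$n_trials,
                                   seed = derive_seed(config$seed, s, 1L)),
                              config$truth_args)
    if (config$truth_type == "planted") {
      do.call(planted_truth, args)
    } else {
      do.call(null_truth, args)
    }
  }

  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    id <- sprintf("sub-%02d", s)
    design <- stage("design", generate_design(
      n_trials = config$n_trials, pairing_rate = config$pairing_rate,
      n_initial_paired = config$n_initial_paired,
      iti_mean_s = config$iti_mean_s, iti_sd_s = config$iti_sd_s,
      block_label = if (config$truth_type == "null") "habituation" else "acquisition",
      seed = derive_seed(config$seed, s, 2L)))
    truth <- make_truth(s)

    per_roi <- vector("list", length(rois))
    names(per_roi) <- rois
    for (k in seq_along(rois)) {
      sim <- stage("simulate_bold", simulate_bold_roi(
        design, truth, n_voxels = config$n_voxels, tr_s = config$tr_s,
        seed = derive_seed(config$seed, s, 10L + k)))
      beta <- stage("beta_series", estimate_beta_series(
        as_roi_timeseries(sim, roi = rois[k], subject = id),
        design, options = config$glm_options))
      split <- stage("split_early_late",
                     split_early_late(beta, t_split_s = config$t_split_s))
      dcur <- stage("differential_curve", differential_curve(
        smooth_curves(beta, bandwidth_trials = config$bandwidth_trials)))
      cp <- stage("change_point", cusum_test(
        dcur$contrast, n_permutations = config$n_permutations,
        threshold = config$cp_threshold,
        seed = derive_seed(config$seed, s, 20L + k)))
      dis <- stage("rsa", window_dissimilarity(
        beta, window = config$rsa_window, step = config$rsa_step))
      per_roi[[k]] <- list(split = split, diff_curve = dcur, cp = cp,
                           dissim = dis,
                           slope = adaptation_slope(dcur),
                           dissim_slope = dissimilarity_slope(dis))
    }

    rr <- stage("simulate_rr", simulate_rr(
      design, truth, baseline_bpm = config$hr_baseline_bpm,
      seed = derive_seed(config$seed, s, 30L)))
    htm <- stage("trial_hr_curves", trial_hr_curves(
      rr, design, window = config$hr_window, bin_s = config$hr_bin_s))
    hrd <- stage("hr_dynamics", hr_dynamics(
      htm, decel_window = config$hr_decel_window,
      bandwidth_trials = config$bandwidth_trials,
      t_split_s = config$t_split_s))

    subjects[[s]] <- list(id = id, design = design, rois = per_roi, hr = hrd)
  }

  # group: early/late paired tests (ROIs + HR), BH across the ROI set
  get_diff <- function(s, roi, per) subjects[[s]]$rois[[roi]]$split$differential[per]
  early <- vapply(rois, function(r) vapply(seq_len(n_sub), get_diff, numeric(1),
                                           roi = r, per = "early"), numeric(n_sub))
  late <- vapply(rois, function(r) vapply(seq_len(n_sub), get_diff, numeric(1),
                                          roi = r, per = "late"), numeric(n_sub))
  hr_early <- vapply(subjects, function(su) su$hr$split$differential["early"], numeric(1))
  hr_late <- vapply(subjects, function(su) su$hr$split$differential["late"], numeric(1))
  el <- stage("early_late_test", early_late_test(
    cbind(early, HR = hr_early), cbind(late, HR = hr_late)))

  # group-mean contrast series and group-level change points per ROI
  group_cp <- lapply(rois, function(r) {
    contrasts <- vapply(subjects, function(su) su$rois[[r]]$diff_curve$contrast,
                        numeric(length(subjects[[1]]$rois[[r]]$diff_curve$contrast)))
    stage("group_change_point", cusum_test(
      rowMeans(contrasts), n_permutations = config$n_permutations,
      threshold = config$cp_threshold,
      seed = derive_seed(config$seed, 0L, 40L + match(r, rois))))
  })
  names(group_cp) <- rois

  cp_matrix <- vapply(rois, function(r) {
    vapply(subjects, function(su) as.numeric(su$rois[[r]]$cp$change_point), numeric(1))
  }, numeric(n_sub))
  hr_diff <- vapply(subjects, function(su) su$hr$acq_diff, numeric(1))
  conc <- stage("roi_concordance", roi_concordance(cp_matrix, covariate = hr_diff))

  # RSA group curves, endpoint tests, and slope concordance for the pattern
  # ROIs against the reference ROI's univariate adaptation slope
  rsa_group <- lapply(rois, function(r) {
    stage("group_curve", group_curve(lapply(subjects, function(su) su$rois[[r]]$dissim)))
  })
  names(rsa_group) <- rois
  endpoints <- lapply(rois, function(r) {
    stage("endpoint_test", endpoint_test(
      lapply(subjects, function(su) su$rois[[r]]$dissim), k = config$endpoint_k))
  })
  names(endpoints) <- rois

  pattern_rois <- if (length(rois) > 1L) rois[-1L] else rois
  slope_matrix <- vapply(pattern_rois, function(r) {
    vapply(subjects, function(su) su$rois[[r]]$dissim_slope, numeric(1))
  }, numeric(n_sub))
  ref_slopes <- vapply(subjects, function(su) su$rois[[rois[1L]]]$slope, numeric(1))
  slopes <- if (length(pattern_rois) >= 2L) {
    stage("slope_concordance", slope_concordance(slope_matrix,
                                                 external_slope = ref_slopes))
  } else NULL

  structure(list(config = config,
                 subjects = subjects,
                 early_late = el,
                 change_points = list(group = group_cp, matrix = cp_matrix),
                 concordance = conc,
                 rsa = list(group_curves = rsa_group, endpoints = endpoints,
                            slope_matrix = slope_matrix),
                 hr = list(acq_diff = hr_diff),
                 slopes = list(reference = ref_slopes, concordance = slopes)),
            class = "fc_report")
}

#' @export
print.fc_report <- function(x, ...) {
  cat(sprintf("<fc_report> %d subjects, ROIs: %s (%s truth, seed %d)\n",
              x$config$n_subjects, paste(x$config$rois, collapse = ", "),
              x$config$truth_type, x$config$seed))
  cat("\nEarly vs late differential (paired t, BH-FDR):\n")
  print(x$early_late, digits = 3)
  cat("\nGroup change points:\n")
  for (r in names(x$change_points$group)) {
    cp <- x$change_points$group[[r]]
    cat(sprintf("  %s: trial %s (confidence %.1f%%)\n",
                r, cp$change_point, cp$confidence))
  }
  cat(sprintf("\nChange-point concordance: F(%d,%d) = %.2f, p = %.3g; PC1 %.0f%%\n",
              x$concordance$df[1], x$concordance$df[2], x$concordance$F,
              x$concordance$p, 100 * x$concordance$eigen_fractions[1]))
  if (!is.na(x$concordance$covariate_r)) {
    cat(sprintf("  PC1 vs HR difference: r = %.2f, p = %.3g\n",
                x$concordance$covariate_r, x$concordance$covariate_p))
  }
  for (r in names(x$rsa$endpoints)) {
    ep <- x$rsa$endpoints[[r]]
    cat(sprintf("RSA endpoint test %s: first %.3f vs last %.3f, t = %.2f, p = %.3g\n",
                r, ep$mean_first, ep$mean_last, ep$t, ep$p))
  }
  if (!is.null(x$slopes$concordance)) {
    sc <- x$slopes$concordance
    cat(sprintf("Slope concordance: PC1 %.0f%%; PC1 vs reference slope r = %.2f, p = %.3g\n",
                100 * sc$eigen_fractions[1], sc$external_r, sc$external_p))
  }
  invisible(x)
}

#' Validate pipeline input files
#'
#' Schema and consistency diagnostics for the on-disk input formats: the
#' events table (columns present, onsets strictly increasing, US onsets on
#' paired trials only), an ROI matrix with its TR sidecar, and RR-interval
#' coverage of every trial's analysis window. Returns issues rather than
#' erroring, so callers can report all problems at once.
#'
#' @param paths A list with any of `events`, `roi_matrix`, `rr` (file
#'   paths).
#' @param hr_window Heart-rate analysis window checked for RR coverage.
#' @return Character vector of issues (empty if everything checks out).
#' @export
validate_inputs <- function(paths, hr_window = c(-1, 5)) {
  issues <- character(0)
  note <- function(...) issues <<- c(issues, sprintf(...))
  events <- NULL
  if (!is.null(paths$events)) {
    if (!file.exists(paths$events)) {
      note("events: file not found: %s", paths$events)
    } else {
      events <- tryCatch(read_events_tsv(paths$events), error = function(e) {
        note("events: %s", conditionMessage(e)); NULL
      })
      if (!is.null(events)) {
        if (any(diff(events$onset) <= 0)) note("events: onsets not strictly increasing")
        known <- c("CSplus_unpaired", "CSplus_paired", "CSminus", "US")
        if (!all(events$condition %in% known)) {
          note("events: unknown trial_type value(s): %s",
               paste(unique(setdiff(events$condition, known)), collapse = ", "))
        }
        paired <- events$condition == "CSplus_paired"
        if (any(paired & is.na(events$us_onset))) {
          note("events: paired trial(s) missing us_onset")
        }
        if (any(!paired & !is.na(events$us_onset))) {
          note("events: us_onset present on non-paired trial(s)")
        }
      }
    }
  }
  if (!is.null(paths$roi_matrix)) {
    if (!file.exists(paths$roi_matrix)) {
      note("roi_matrix: file not found: %s", paths$roi_matrix)
    } else {
      m <- tryCatch(read_roi_matrix(paths$roi_matrix), error = function(e) {
        note("roi_matrix: %s", conditionMessage(e)); NULL
      })
      if (!is.null(m)) {
        if (is.na(m$tr_s)) note("roi_matrix: sidecar missing tr_s")
        if (anyNA(m$data)) note("roi_matrix: missing values in the matrix")
        if (!is.null(events) && !is.na(m$tr_s) &&
            max(events$onset) >= ncol(m$data) * m$tr_s) {
          note("roi_matrix: run shorter than the last trial onset")
        }
      }
    }
  }
  if (!is.null(paths$rr)) {
    if (!file.exists(paths$rr)) {
      note("rr: file not found: %s", paths$rr)
    } else {
      rr <- tryCatch(read_rr(paths$rr), error = function(e) {
        note("rr: %s", conditionMessage(e)); NULL
      })
      if (!is.null(rr) && !is.null(events)) {
        last_needed <- max(events$onset) + hr_window[2]
        if (rr$duration_s < last_needed) {
          note("rr: recording (%.1f s) does not cover all trial windows (need %.1f s)",
               rr$duration_s, last_needed)
        }
      }
    }
  }
  issues
}
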