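#' Generate a conditioning block design
#'
#' Builds the trial timeline of one differential-conditioning block: equal
#' numbers of CS+ and CS- trials in pseudo-random order (no more than
#' `max_run` consecutive trials of one condition), a fixed number of initial
#' CS+ trials that are always reinforced, exact-count reinforcement of the
#' remaining CS+ trials, and intertrial intervals drawn from a truncated
#' normal distribution.
#'
#' The defaults reproduce the acquisition paradigm: 120 trials, the first 4
#' CS+ trials paired with the unconditioned stimulus (US), 25% of the
#' remaining CS+ trials paired, 1-s CS presentation, US onset 0.5 s after CS
#' onset, and ITIs of 4.6 +/- 1.5 s. Reinforcement is assigned by exact count
#' (`round(pairing_rate * n_remaining)` trials), not by independent coin
#' flips, so the nominal rate is realised in every generated block.
#'
#' @param n_trials Total number of trials (even, >= 2). Half CS+, half CS-.
#' @param pairing_rate Fraction of post-initial CS+ trials paired with the US.
#' @param n_initial_paired Number of leading CS+ trials that are always paired.
#' @param iti_mean_s,iti_sd_s Mean and SD of the intertrial interval (s).
#' @param iti_floor_s Lower truncation bound for the ITI distribution (s).
#' @param cs_duration_s CS presentation time for unpaired trials (s).
#' @param us_lag_s US onset relative to CS onset on paired trials (s).
#' @param us_duration_s US duration (s); CS and US co-terminate on paired
#'   trials, so a paired trial spans `us_lag_s + us_duration_s`.
#' @param max_run Maximum number of consecutive same-condition trials.
#' @param block_label `"acquisition"` or `"habituation"` (bookkeeping only).
#' @param seed Integer seed; the design is a deterministic function of its
#'   arguments.
#' @return An object of class `fc_design`: a data.frame with columns
#'   `trial`, `onset`, `duration`, `condition`
#'   (`CSplus_unpaired`/`CSplus_paired`/`CSminus`) and `us_onset` (`NA` for
#'   unreinforced trials), with the ITI draws, block label and total duration
#'   stored as attributes.
#' @examples
#' d <- generate_design(seed = 1)
#' table(cs_condition(d))
#' @export
generate_design <- function(n_trials = 120L,
                            pairing_rate = 0.25,
                            n_initial_paired = 4L,
                            iti_mean_s = 4.6,
                            iti_sd_s = 1.5,
                            iti_floor_s = 1.5,
                            cs_duration_s = 1,
                            us_lag_s = 0.5,
                            us_duration_s = 1,
                            max_run = 4L,
                            block_label = c("acquisition", "habituation"),
                            seed) {
  block_label <- match.arg(block_label)
  if (missing(seed)) stop("'seed' must be supplied: designs are reproducible by contract")
  if (n_trials < 2L || n_trials %% 2L != 0L) stop("'n_trials' must be even and >= 2")
  if (pairing_rate < 0 || pairing_rate > 1) stop("'pairing_rate' must be in [0, 1]")
  if (iti_sd_s < 0) stop("'iti_sd_s' must be >= 0")
  if (iti_floor_s < 0) stop("ITI floor must be non-negative")
  n_per <- n_trials %/% 2L

  set.seed(as.integer(seed))
  cond <- sample_balanced_sequence(n_per, max_run = max_run)

  # reinforcement: first n_initial_paired CS+ trials always paired, then an
  # exact count round(pairing_rate * remainder) among the rest
  csp_idx <- which(cond == "CSplus")
  n_initial_paired <- min(as.integer(n_initial_paired), n_per)
  paired <- logical(n_trials)
  if (n_initial_paired > 0L) paired[csp_idx[seq_len(n_initial_paired)]] <- TRUE
  rest <- if (n_initial_paired > 0L) csp_idx[-seq_len(n_initial_paired)] else csp_idx
  n_rest_paired <- as.integer(round(pairing_rate * length(rest)))
  if (pairing_rate > 0 && length(rest) > 0L && n_rest_paired == 0L) {
    warning("pairing_rate > 0 but it rounds to 0 paired trials among the ",
            length(rest), " post-initial CS+ trials")
  }
  if (n_rest_paired > 0L) paired[sample(rest, n_rest_paired)] <- TRUE

  condition <- ifelse(cond == "CSminus", "CSminus",
                      ifelse(paired, "CSplus_paired", "CSplus_unpaired"))

  iti <- rtruncnorm(n_trials, iti_mean_s, iti_sd_s, lower = iti_floor_s)
  span <- ifelse(condition == "CSplus_paired", us_lag_s + us_duration_s, cs_duration_s)
  onset <- numeric(n_trials)
  onset[1] <- iti[1]
  if (n_trials > 1L) {
    for (i in 2:n_trials) onset[i] <- onset[i - 1] + span[i - 1] + iti[i]
  }

  trials <- data.frame(
    trial = seq_len(n_trials),
    onset = onset,
    duration = rep(cs_duration_s, n_trials),
    condition = condition,
    us_onset = ifelse(condition == "CSplus_paired", onset + us_lag_s, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(trials,
            class = c("fc_design", "data.frame"),
            block_label = block_label,
            iti = iti,
            iti_mean_s = iti_mean_s,
            iti_sd_s = iti_sd_s,
            iti_floor_s = iti_floor_s,
            cs_duration_s = cs_duration_s,
            us_lag_s = us_lag_s,
            total_duration_s = onset[n_trials] + span[n_trials],
            seed = as.integer(seed))
}

# balanced two-condition sequence with bounded run lengths; sequential
# sampling with restart on the (rare) dead end where one condition runs out
sample_balanced_sequence <- function(n_per, max_run = 4L, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    remaining <- c(CSplus = n_per, CSminus = n_per)
    out <- character(2L * n_per)
    run <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      feasible <- names(remaining)[remaining > 0L]
      if (run >= max_run && length(feasible) > 1L) {
        feasible <- setdiff(feasible, out[i - 1L])
      } else if (run >= max_run && length(feasible) == 1L &&
                 i > 1L && feasible == out[i - 1L]) {
        ok <- FALSE
        break
      }
      pick <- if (length(feasible) == 1L) feasible else {
        sample(feasible, 1L, prob = remaining[feasible])
      }
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      run <- if (i > 1L && out[i - 1L] == pick) run + 1L else 1L
    }
    if (ok) return(out)
  }
  stop("could not generate a balanced sequence with max run ", max_run)
}

rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    keep <- draw >= lower
    out[need[keep]] <- draw[keep]
    need <- need[!keep]
  }
  out
}

#' @export
print.fc_design <- function(x, ...) {
  cat(sprintf("<fc_design> %s block: %d trials (%d CS+ of which %d paired, %d CS-)\n",
              attr(x, "block_label"), nrow(x),
              sum(x$condition != "CSminus"),
              sum(x$condition == "CSplus_paired"),
              sum(x$condition == "CSminus")))
  cat(sprintf("  duration %.1f s, mean ITI %.2f s\n",
              attr(x, "total_duration_s"), mean(attr(x, "iti"))))
  invisible(x)
}

#' Condition of each trial, collapsed to CS+/CS-
#' @param design An `fc_design`.
#' @return Character vector, `"CSplus"` or `"CSminus"` per trial.
#' @export
cs_condition <- function(design) {
  ifelse(design$condition == "CSminus", "CSminus", "CSplus")
}

#' Trials retained for analysis
#'
#' Reinforced (paired) CS+ trials are excluded from all response analyses
#' because the US-evoked activity contaminates the CS+ response.
#'
#' @param design An `fc_design` (or any data.frame with a `condition` column).
#' @return The subset of rows with condition `CSplus_unpaired` or `CSminus`,
#'   in chronological order.
#' @export
analysed_trials <- function(design) {
  design[design$condition %in% c("CSplus_unpaired", "CSminus"), , drop = FALSE]
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with header `onset duration trial_type us_onset`; times in
#' seconds with 3 decimals, missing US onsets written as `n/a`.
#'
#' @param design An `fc_design`.
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a data.frame with the design columns (attributes such as the ITI
#'   draws are not round-tripped).
#' @export
write_events_tsv <- function(design, path) {
  df <- data.frame(
    onset = sprintf("%.3f", design$onset),
    duration = sprintf("%.3f", design$duration),
    trial_type = design$condition,
    us_onset = ifelse(is.na(design$us_onset), "n/a", sprintf("%.3f", design$us_onset)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "n/a", stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type")
  if (!all(req %in% names(df))) {
    stop("events table must have columns: ", paste(req, collapse = ", "))
  }
  out <- data.frame(
    trial = seq_len(nrow(df)),
    onset = as.numeric(df$onset),
    duration = as.numeric(df$duration),
    condition = as.character(df$trial_type),
    us_onset = if ("us_onset" %in% names(df)) as.numeric(df$us_onset) else NA_real_,
    stringsAsFactors = FALSE
  )
  out
}
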