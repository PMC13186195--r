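#' Study design configuration
#'
#' Every numeric constant of the study design lives here so that each analysis
#' stage reads its windows and thresholds from a single, validated object.
#' The defaults encode the design used throughout the package: at least three
#' prescriptions at most 120 days apart within a 365-day span, a 180-day
#' prescription-free washout defining discontinuation, a +/-90-day baseline
#' window around the index date, a 180-day follow-up window, 30-day trajectory
#' bins, and a 2% weight-regain threshold.
#'
#' Calendar months are operationalized as round day counts ("4 months" = 120
#' days, "6 months" = 180 days, "12 months" = 365 days); all date arithmetic
#' is in whole days.
#'
#' @param study_start,study_end Calendar bounds (`Date` or "YYYY-MM-DD"
#'   strings) on qualifying prescriptions and index dates. Weight
#'   measurements are not restricted to this period.
#' @param min_prescriptions Minimum prescriptions in a qualifying run.
#' @param max_gap_days Maximum gap, in days, between successive prescriptions
#'   of a qualifying run.
#' @param span_days Maximum first-to-last span, in days, of a qualifying run.
#' @param washout_days Prescription-free days required after the index date
#'   for the patient to count as discontinued.
#' @param baseline_window_days Half-width, in days, of the window around the
#'   index date searched for the baseline weight.
#' @param followup_days Length, in days, of the post-index follow-up window
#'   used for regain classification and the follow-up change statistic.
#' @param bin_width_days Width, in days, of trajectory bins.
#' @param pre_window_days Days before the index date included in trajectory
#'   analysis (the analysis window is `[-pre_window_days, followup_days]`).
#' @param regain_threshold_pct Percent weight increase over baseline at or
#'   above which a patient is labelled "regain".
#' @param ci_multiplier Multiplier on the standard error of the mean for
#'   confidence intervals (1.96 for 95% intervals).
#' @param notes_discont_window_days Half-width, in days, of the window around
#'   the index date within which a discontinuation note event counts as
#'   clinician-documented discontinuation.
#' @param notes_restart_min_days Minimum days after the index date for a
#'   restart/switch note event to count as a post-index restart.
#' @param notes_horizon_days Half-width, in days, of the note-selection
#'   horizon around the index date; events outside it are ignored.
#' @param maintenance_lookback_days Days before (and including) the index
#'   date searched for a maintenance-dose prescription.
#'
#' @return A validated list with class `"study_config"`.
#' @examples
#' cfg <- study_config()
#' cfg$washout_days
#' @export
study_config <- function(study_start = "2019-01-08",
                         study_end = "2025-01-07",
                         min_prescriptions = 3L,
                         max_gap_days = 120L,
                         span_days = 365L,
                         washout_days = 180L,
                         baseline_window_days = 90L,
                         followup_days = 180L,
                         bin_width_days = 30L,
                         pre_window_days = 365L,
                         regain_threshold_pct = 2.0,
                         ci_multiplier = 1.96,
                         notes_discont_window_days = 90L,
                         notes_restart_min_days = 60L,
                         notes_horizon_days = 365L,
                         maintenance_lookback_days = 365L) {
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    min_prescriptions = as.integer(min_prescriptions),
    max_gap_days = as.integer(max_gap_days),
    span_days = as.integer(span_days),
    washout_days = as.integer(washout_days),
    baseline_window_days = as.integer(baseline_window_days),
    followup_days = as.integer(followup_days),
    bin_width_days = as.integer(bin_width_days),
    pre_window_days = as.integer(pre_window_days),
    regain_threshold_pct = as.numeric(regain_threshold_pct),
    ci_multiplier = as.numeric(ci_multiplier),
    notes_discont_window_days = as.integer(notes_discont_window_days),
    notes_restart_min_days = as.integer(notes_restart_min_days),
    notes_horizon_days = as.integer(notes_horizon_days),
    maintenance_lookback_days = as.integer(maintenance_lookback_days)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  day_fields <- c(
    "min_prescriptions", "max_gap_days", "span_days", "washout_days",
    "baseline_window_days", "followup_days", "bin_width_days",
    "pre_window_days", "notes_discont_window_days", "notes_restart_min_days",
    "notes_horizon_days", "maintenance_lookback_days"
  )
  for (f in day_fields) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      abort(sprintf("study_config field '%s' must be a positive integer", f),
            class = "glp1traj_config_error")
    }
  }
  if (is.na(cfg$study_start) || is.na(cfg$study_end) ||
      cfg$study_start >= cfg$study_end) {
    abort("study_start must precede study_end",
          class = "glp1traj_config_error")
  }
  if (!is.finite(cfg$regain_threshold_pct) || cfg$regain_threshold_pct <= 0) {
    abort("regain_threshold_pct must be > 0", class = "glp1traj_config_error")
  }
  if (!is.finite(cfg$ci_multiplier) || cfg$ci_multiplier < 0) {
    abort("ci_multiplier must be non-negative",
          class = "glp1traj_config_error")
  }
  invisible(cfg)
}

#' Read or write a study configuration as flat JSON
#'
#' The on-disk format is a flat key-value JSON object whose keys mirror the
#' [study_config()] arguments; absent keys fall back to the defaults.
#'
#' @param path Path to a JSON file.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "glp1traj_file_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown study_config keys: %s",
                  paste(unknown, collapse = ", ")),
          class = "glp1traj_config_error")
  }
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param cfg A `study_config` object.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  out <- unclass(cfg)
  out$study_start <- format(out$study_start)
  out$study_end <- format(out$study_end)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}
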