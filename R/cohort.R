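## Eligibility, index dates and baselines from prescription timelines.
##
## Terminology: a "qualifying run" is >= min_prescriptions prescriptions,
## consecutive in the patient's (deduplicated) timeline, with successive gaps
## <= max_gap_days, first-to-last span <= span_days, all inside the study
## period. The index date is the earliest in-period prescription date, at or
## after the end of some qualifying run, followed by >= washout_days with no
## study-drug prescription. The washout considers ALL of the patient's
## prescriptions (a fill outside the study period is still evidence of
## continued therapy); a prescription exactly washout_days after a candidate
## breaks the washout ("at least" read inclusively).

rx_dates_of <- function(prescriptions) {
  if (is.data.frame(prescriptions)) prescriptions$date else prescriptions
}

## earliest end date of a qualifying run, or NULL; also reports the failure
## mode when no run exists. Works on sorted unique in-period dates.
earliest_run_end <- function(d, cfg) {
  m <- cfg$min_prescriptions
  n <- length(d)
  if (n < m) return(list(end = NULL, reason = "too_few_rx"))
  gaps <- as.integer(diff(d))
  seg <- cumsum(c(0L, gaps > cfg$max_gap_days))
  i <- seq_len(n - m + 1L)
  j <- i + m - 1L
  ok <- seg[i] == seg[j] & as.integer(d[j] - d[i]) <= cfg$span_days
  if (!any(ok)) {
    reason <- if (all(seg[i] != seg[j])) "gap_too_wide" else "span_too_long"
    return(list(end = NULL, reason = reason))
  }
  list(end = min(d[j][ok]), reason = NA_character_)
}

## candidate index dates given the earliest run end; all_dates break washouts
index_candidates <- function(d_period, all_dates, run_end, cfg) {
  cand <- d_period[d_period >= run_end]
  if (!length(cand)) return(cand[0])
  ok <- vapply(cand, function(t) {
    !any(all_dates > t & all_dates <= t + cfg$washout_days)
  }, logical(1))
  cand[ok]
}

patient_rx_days <- function(prescriptions, cfg) {
  d <- sort(unique(rx_dates_of(prescriptions)))
  list(all = d,
       period = d[d >= cfg$study_start & d <= cfg$study_end])
}

#' Eligibility of one patient's prescription timeline
#'
#' Applies the inclusion rules to a single patient's prescriptions: a
#' qualifying run of at least `min_prescriptions` prescriptions with
#' successive gaps at most `max_gap_days` and span at most `span_days`
#' inside the study period, followed by a prescription-free washout of at
#' least `washout_days`. Patients with prescriptions for both study drugs
#' are ineligible ("switcher"). Duplicate same-day prescriptions are
#' collapsed before gap analysis.
#'
#' @param prescriptions A tibble of one patient's prescriptions (columns
#'   `date` and, for the switcher rule, `ingredient`), or a `Date` vector.
#' @param config A [study_config()].
#' @return A list with `eligible` (logical) and `reason` (`"eligible"` or
#'   the first failing rule: `"no_rx"`, `"switcher"`, `"too_few_rx"`,
#'   `"gap_too_wide"`, `"span_too_long"`, `"no_washout"`).
#' @export
check_eligibility <- function(prescriptions, config = study_config()) {
  if (is.data.frame(prescriptions) && "ingredient" %in% names(prescriptions)) {
    drugs <- unique(prescriptions$ingredient)
    if (length(drugs) > 1L) {
      return(list(eligible = FALSE, reason = "switcher"))
    }
  }
  dd <- patient_rx_days(prescriptions, config)
  if (length(dd$all) == 0L) return(list(eligible = FALSE, reason = "no_rx"))
  run <- earliest_run_end(dd$period, config)
  if (is.null(run$end)) return(list(eligible = FALSE, reason = run$reason))
  cand <- index_candidates(dd$period, dd$all, run$end, config)
  if (!length(cand)) return(list(eligible = FALSE, reason = "no_washout"))
  list(eligible = TRUE, reason = "eligible")
}

#' Index date of one eligible patient
#'
#' The earliest in-period prescription date `t` such that a qualifying run
#' ends at or before `t` and no study-drug prescription falls in
#' `(t, t + washout_days]`. A later prescribing episode after the washout is
#' ignored; if the washout after the first run is broken, the index moves
#' forward to the first prescription that is followed by silence.
#'
#' @inheritParams check_eligibility
#' @return A `Date` (always one of the patient's prescription dates).
#' @export
find_index_date <- function(prescriptions, config = study_config()) {
  dd <- patient_rx_days(prescriptions, config)
  run <- earliest_run_end(dd$period, config)
  if (is.null(run$end)) {
    abort("find_index_date called on an ineligible patient",
          class = "glp1traj_eligibility_error")
  }
  cand <- index_candidates(dd$period, dd$all, run$end, config)
  if (!length(cand)) {
    abort("find_index_date called on an ineligible patient (no washout)",
          class = "glp1traj_eligibility_error")
  }
  min(cand)
}

#' Baseline weight for a known index date
#'
#' The baseline is the weight measurement minimizing `|date - index_date|`
#' within `baseline_window_days`; an exact tie between a pre- and post-index
#' measurement resolves to the earlier one. Patients without a baseline, or
#' without a post-index measurement (other than the baseline itself) inside
#' the follow-up window, are rejected with reason codes rather than errors.
#'
#' @param index_date The patient's index date (`Date`).
#' @param weights Tibble of the patient's weight measurements (`date`,
#'   `weight_kg`).
#' @param config A [study_config()].
#' @return A list with `ok`; on success `baseline_weight_kg` and
#'   `baseline_date`, otherwise `reason` (`"no_baseline"` or
#'   `"no_followup_weight"`).
#' @export
attach_baseline <- function(index_date, weights, config = study_config()) {
  off <- as.integer(weights$date - index_date)
  in_window <- abs(off) <= config$baseline_window_days
  if (!any(in_window)) return(list(ok = FALSE, reason = "no_baseline"))
  wo <- off[in_window]
  ord <- order(abs(wo), wo)  # nearest first; earlier wins exact ties
  pick <- which(in_window)[ord[1L]]
  post <- off > 0L & off <= config$followup_days &
    weights$date != weights$date[pick]
  if (!any(post)) return(list(ok = FALSE, reason = "no_followup_weight"))
  list(ok = TRUE,
       baseline_weight_kg = weights$weight_kg[pick],
       baseline_date = weights$date[pick])
}

#' Build the discontinuation cohort
#'
#' Runs eligibility, index-date and baseline attachment over every patient in
#' the prescriptions table and returns one index record per accepted patient
#' together with a rejection ledger that accounts for every input patient.
#' Rejection reasons are evaluated in a fixed order (no_rx, switcher,
#' run-structure failures, no_washout, no_baseline, no_followup_weight) and
#' record the first failing rule only.
#'
#' @param prescriptions Validated prescriptions tibble (all patients).
#' @param weights Validated weights tibble.
#' @param config A [study_config()].
#' @return A tibble with class `"glp1_cohort"` and columns `patient_id`,
#'   `drug`, `index_date`, `baseline_weight_kg`, `baseline_date`,
#'   `n_qualifying_rx`; the ledger is attached as attribute `"ledger"` (see
#'   [cohort_ledger()]).
#' @examples
#' sim <- simulate_ehr(sim_config(n_patients = 30, seed = 7))
#' cohort <- build_cohort(sim$prescriptions, sim$weights)
#' table(cohort_ledger(cohort)$reason)
#' @export
build_cohort <- function(prescriptions, weights, config = study_config()) {
  by_pt <- split(prescriptions, prescriptions$patient_id)
  wt_by_pt <- split(weights, weights$patient_id)
  rows <- vector("list", length(by_pt))
  ledger <- vector("list", length(by_pt))
  for (k in seq_along(by_pt)) {
    pid <- names(by_pt)[k]
    rx <- by_pt[[k]]
    elig <- check_eligibility(rx, config)
    if (!elig$eligible) {
      ledger[[k]] <- tibble(patient_id = pid, status = "rejected",
                            reason = elig$reason)
      next
    }
    idx <- find_index_date(rx, config)
    wt <- wt_by_pt[[pid]]
    if (is.null(wt)) wt <- tibble(date = as.Date(character(0)),
                                  weight_kg = numeric(0))
    base <- attach_baseline(idx, wt, config)
    if (!base$ok) {
      ledger[[k]] <- tibble(patient_id = pid, status = "rejected",
                            reason = base$reason)
      next
    }
    dd <- patient_rx_days(rx, config)
    rows[[k]] <- tibble(
      patient_id = pid,
      drug = rx$ingredient[1L],
      index_date = idx,
      baseline_weight_kg = base$baseline_weight_kg,
      baseline_date = base$baseline_date,
      n_qualifying_rx = sum(dd$period <= idx)
    )
    ledger[[k]] <- tibble(patient_id = pid, status = "accepted",
                          reason = "accepted")
  }
  cohort <- dplyr::bind_rows(rows)
  if (nrow(cohort) == 0L) {
    cohort <- tibble(patient_id = character(0), drug = character(0),
                     index_date = as.Date(character(0)),
                     baseline_weight_kg = numeric(0),
                     baseline_date = as.Date(character(0)),
                     n_qualifying_rx = integer(0))
  }
  attr(cohort, "ledger") <- dplyr::bind_rows(ledger)
  class(cohort) <- c("glp1_cohort", class(cohort))
  cohort
}

#' Rejection ledger of a cohort
#'
#' @param cohort A cohort from [build_cohort()].
#' @return A tibble mapping every input patient to `"accepted"` or the first
#'   failing eligibility reason.
#' @export
cohort_ledger <- function(cohort) {
  led <- attr(cohort, "ledger", exact = TRUE)
  if (is.null(led)) {
    abort("object has no ledger; was it produced by build_cohort()?",
          class = "glp1traj_ledger_error")
  }
  led
}
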