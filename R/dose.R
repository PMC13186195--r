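#' Minimum labeled maintenance doses per brand
#'
#' The minimum labeled therapeutic ("maintenance") dose of each brand
#' formulation, in mg: Ozempic 0.5, Wegovy 1.7, Rybelsus 7, Mounjaro 5,
#' Zepbound 5. Thresholds differ by brand even within an ingredient, so an
#' unknown brand can never be scored.
#'
#' @return A named numeric vector (mg).
#' @export
maintenance_thresholds <- function() {
  c(Ozempic = 0.5, Wegovy = 1.7, Rybelsus = 7, Mounjaro = 5, Zepbound = 5)
}

#' Maintenance-dose attainment for one patient
#'
#' `TRUE` iff at least one prescription dated within the closed window
#' `[index_date - maintenance_lookback_days, index_date]` has a known brand,
#' a recorded dose, and `dose_mg` at or above that brand's threshold.
#' Prescriptions with unknown brand or absent dose never qualify.
#'
#' @param prescriptions Tibble of one patient's prescriptions (`brand`,
#'   `dose_mg`, `date`).
#' @param index_date The patient's index date.
#' @param thresholds Named dose thresholds, mg (see
#'   [maintenance_thresholds()]).
#' @param config A [study_config()].
#' @return Logical scalar.
#' @export
attained_maintenance <- function(prescriptions, index_date,
                                 thresholds = maintenance_thresholds(),
                                 config = study_config()) {
  rx <- prescriptions
  in_win <- rx$date >= index_date - config$maintenance_lookback_days &
    rx$date <= index_date
  known <- rx$brand %in% names(thresholds) & !is.na(rx$dose_mg)
  any(in_win & known & rx$dose_mg >= thresholds[rx$brand], na.rm = TRUE)
}

#' Per-patient maintenance attainment over a cohort
#'
#' @param cohort A cohort from [build_cohort()].
#' @param prescriptions Validated prescriptions tibble (all patients).
#' @inheritParams attained_maintenance
#' @return A tibble `patient_id`, `drug`, `attained`; the number of
#'   prescriptions skipped for unknown brand or missing dose is attached as
#'   attribute `"n_unscoreable"`.
#' @export
maintenance_attainment <- function(cohort, prescriptions,
                                   thresholds = maintenance_thresholds(),
                                   config = study_config()) {
  rx_by_pt <- split(as_tibble(prescriptions), prescriptions$patient_id)
  co <- as_tibble(cohort)
  att <- purrr::map2_lgl(co$patient_id, co$index_date, function(pid, idx) {
    rx <- rx_by_pt[[pid]]
    attained_maintenance(rx, idx, thresholds, config)
  })
  out <- tibble(patient_id = co$patient_id, drug = co$drug, attained = att)
  cohort_rx <- prescriptions[prescriptions$patient_id %in% co$patient_id, ]
  attr(out, "n_unscoreable") <- sum(!cohort_rx$brand %in% names(thresholds) |
                                      is.na(cohort_rx$dose_mg))
  out
}

#' Maintenance attainment rate per drug
#'
#' Percentage of cohort patients with at least one maintenance-level
#' prescription in the pre-index year, with the full drug cohort as
#' denominator.
#'
#' @inheritParams maintenance_attainment
#' @return A tibble: `drug`, `n`, `n_attained`, `rate_pct`.
#' @export
maintenance_rate <- function(cohort, prescriptions,
                             thresholds = maintenance_thresholds(),
                             config = study_config()) {
  if (nrow(cohort) == 0L) {
    abort("cannot compute maintenance rates on an empty cohort",
          class = "glp1traj_empty_cohort_error")
  }
  maintenance_attainment(cohort, prescriptions, thresholds, config) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(n = dplyr::n(),
                     n_attained = sum(.data$attained),
                     rate_pct = 100 * sum(.data$attained) / dplyr::n(),
                     .groups = "drop")
}
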