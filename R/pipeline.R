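#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage end-to-end: generate a synthetic EHR extract, build
#' the discontinuation cohort, compute trajectory points and two-stage bin
#' aggregates (per drug and per drug-by-outcome group), classify regain,
#' score maintenance-dose attainment, roll up note events, and produce the
#' cohort characteristics table, note summary table, counseling comparisons
#' and the follow-up change histogram.
#'
#' @param sim A [sim_config()]; `seed` (if given) overrides `sim$seed`.
#' @param study A [study_config()].
#' @param seed Optional integer seed overriding `sim$seed`.
#' @return A list with class `"glp1_study"`: `simulation`, `cohort`,
#'   `ledger`, `points`, `bins_by_drug`, `bins_by_group`, `labels`,
#'   `maintenance`, `note_summaries`, `table1`, `table2`, `comparisons`,
#'   `histogram`, `config`. See [glance.glp1_study()].
#' @examples
#' \donttest{
#' res <- run_weight_study(sim_config(n_patients = 200), seed = 42)
#' glance(res)
#' }
#' @export
run_weight_study <- function(sim = sim_config(), study = study_config(),
                             seed = NULL) {
  if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
  }
  simulation <- simulate_ehr(sim, study)
  cohort <- build_cohort(simulation$prescriptions, simulation$weights, study)
  points <- patient_trajectories(cohort, simulation$weights, study)
  labels <- classify_regain(cohort, simulation$weights, study)
  points_lab <- dplyr::left_join(points,
                                 labels[, c("patient_id", "label")],
                                 by = "patient_id")
  structure(list(
    simulation = simulation,
    cohort = cohort,
    ledger = cohort_ledger(cohort),
    points = points,
    bins_by_drug = aggregate_bins(points, study, "drug"),
    bins_by_group = aggregate_bins(points_lab, study, "drug",
                                   "label"),
    labels = labels,
    maintenance = maintenance_rate(cohort, simulation$prescriptions,
                                   config = study),
    note_summaries = summarize_notes(simulation$note_events, cohort, study),
    table1 = table1_summary(simulation$demographics, cohort,
                            simulation$weights, study),
    table2 = table2_summary(summarize_notes(simulation$note_events, cohort,
                                            study), labels),
    comparisons = counseling_comparison(
      summarize_notes(simulation$note_events, cohort, study), labels),
    histogram = followup_histogram(labels),
    config = study
  ), class = "glp1_study")
}

#' @export
print.glp1_study <- function(x, ...) {
  cat(sprintf("<glp1_study> %d accepted patients (%d rejected)\n",
              nrow(x$cohort), sum(x$ledger$status == "rejected")))
  print(glance(x))
  invisible(x)
}

#' Headline numbers of a pipeline run
#'
#' @param x A `"glp1_study"` from [run_weight_study()].
#' @param ... Unused.
#' @return A one-row tibble: cohort sizes, regain percentage and
#'   maintenance attainment per drug, mean/median follow-up change, and the
#'   counseling percentages with their p-values.
#' @method glance glp1_study
#' @export
glance.glp1_study <- function(x, ...) {
  by_drug <- x$labels |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(n = dplyr::n(),
                     regain_pct = 100 * mean(.data$label == "regain"),
                     .groups = "drop")
  g <- function(df, drug, col) {
    v <- df[[col]][df$drug == drug]
    if (length(v)) v else NA_real_
  }
  ex <- x$comparisons[x$comparisons$counseling == "exercise", ]
  dt <- x$comparisons[x$comparisons$counseling == "diet", ]
  tibble(
    n_semaglutide = as.integer(g(by_drug, "semaglutide", "n")),
    n_tirzepatide = as.integer(g(by_drug, "tirzepatide", "n")),
    regain_pct_semaglutide = g(by_drug, "semaglutide", "regain_pct"),
    regain_pct_tirzepatide = g(by_drug, "tirzepatide", "regain_pct"),
    followup_mean_pct = x$histogram$mean,
    followup_median_pct = x$histogram$median,
    maintenance_pct_semaglutide = g(x$maintenance, "semaglutide",
                                    "rate_pct"),
    maintenance_pct_tirzepatide = g(x$maintenance, "tirzepatide",
                                    "rate_pct"),
    exercise_pct_non_regain = ex$pct_non_regain,
    exercise_pct_regain = ex$pct_regain,
    exercise_p_value = ex$p_value,
    diet_pct_non_regain = dt$pct_non_regain,
    diet_pct_regain = dt$pct_regain,
    diet_p_value = dt$p_value
  )
}

#' Write a study report as CSV files
#'
#' Writes `cohort.csv`, `ledger.csv`, `bins.csv`, `bins_by_group.csv`,
#' `labels.csv`, `maintenance.csv`, `table1.csv`, `table2.csv`,
#' `comparisons.csv` and `histogram.csv` under `dir`.
#'
#' @param x A `"glp1_study"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(x, dir) {
  stopifnot(inherits(x, "glp1_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(as_tibble(df), file.path(dir, name), progress = FALSE)
  }
  w(x$cohort, "cohort.csv")
  w(x$ledger, "ledger.csv")
  w(x$bins_by_drug, "bins.csv")
  w(x$bins_by_group, "bins_by_group.csv")
  w(x$labels, "labels.csv")
  w(x$maintenance, "maintenance.csv")
  w(x$table1, "table1.csv")
  w(x$table2, "table2.csv")
  w(x$comparisons, "comparisons.csv")
  w(tidy(x$histogram), "histogram.csv")
  invisible(dir)
}
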