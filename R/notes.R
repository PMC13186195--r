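note_flag_cols <- c(
  "has_post_notes", "discontinuation_documented", "restart_or_switch_post60",
  "outside_source", "other_aom", "weight_status_documented",
  "diet_counseling_post", "exercise_counseling_post"
)

#' Patient-level indicators from note-level events
#'
#' Rolls structured note events (the output of an upstream extraction step)
#' up to per-patient flags relative to the index date. Events outside the
#' note-selection horizon (`index +/- notes_horizon_days`) are ignored.
#' Within the horizon: a discontinuation event within
#' `+/- notes_discont_window_days` of the index sets
#' `discontinuation_documented`; a restart or switch event strictly more
#' than `notes_restart_min_days` after the index sets
#' `restart_or_switch_post60`; the follow-up flags (outside source, other
#' anti-obesity medication, weight status, diet/exercise counseling) require
#' an event strictly after the index. A patient with no events has all flags
#' `FALSE`. Flags are invariant to event order and duplication, and adding
#' an event can only set flags, never unset them.
#'
#' @param note_events Validated note-events tibble (all patients).
#' @param cohort A cohort from [build_cohort()] (one output row per cohort
#'   patient, whether or not they have events).
#' @param config A [study_config()].
#' @return A tibble: `patient_id` plus the logical indicator columns.
#' @export
summarize_notes <- function(note_events, cohort, config = study_config()) {
  co <- as_tibble(cohort)[, c("patient_id", "index_date")]
  ev <- dplyr::inner_join(as_tibble(note_events), co, by = "patient_id") |>
    dplyr::mutate(d = as.integer(.data$note_date - .data$index_date)) |>
    dplyr::filter(abs(.data$d) <= config$notes_horizon_days)
  flags <- ev |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_post_notes = any(.data$d > 0L),
      discontinuation_documented = any(
        .data$event_type == "discontinuation" &
          abs(.data$d) <= config$notes_discont_window_days),
      restart_or_switch_post60 = any(
        .data$event_type %in% c("restart", "switch") &
          .data$d > config$notes_restart_min_days),
      outside_source = any(.data$event_type == "outside_source" &
                             .data$d > 0L),
      other_aom = any(.data$event_type == "other_aom" & .data$d > 0L),
      weight_status_documented = any(.data$event_type == "weight_status" &
                                       .data$d > 0L),
      diet_counseling_post = any(.data$event_type == "diet_counseling" &
                                   .data$d > 0L),
      exercise_counseling_post = any(
        .data$event_type == "exercise_counseling" & .data$d > 0L),
      .groups = "drop"
    )
  dplyr::left_join(co["patient_id"], flags, by = "patient_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(note_flag_cols),
                                \(x) dplyr::coalesce(x, FALSE)))
}

#' Note-indicator summary by drug and outcome group
#'
#' Counts and percentages of each patient-level note indicator, per
#' drug-by-outcome cell plus a totals column over the full curated set; each
#' percentage uses its own cell's group size as denominator.
#'
#' @param summaries Output of [summarize_notes()].
#' @param labels Output of [classify_regain()] covering every summarized
#'   patient (supplies both `drug` and `label`).
#' @return A tibble in long form: `measure`, `group` (e.g. `"total"`,
#'   `"semaglutide_non_regain"`), `group_n`, `count`, `pct`.
#' @export
table2_summary <- function(summaries, labels) {
  joined <- dplyr::left_join(as_tibble(summaries),
                             as_tibble(labels)[, c("patient_id", "drug",
                                                   "label")],
                             by = "patient_id")
  if (any(is.na(joined$drug)) || any(is.na(joined$label))) {
    abort("every summarized patient needs a drug and a regain label",
          class = "glp1traj_label_error")
  }
  cell_counts <- function(df, group) {
    tidyr::pivot_longer(df[note_flag_cols], dplyr::everything(),
                        names_to = "measure", values_to = "flag") |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(group_n = nrow(df), count = sum(.data$flag),
                       pct = 100 * sum(.data$flag) / nrow(df),
                       .groups = "drop") |>
      dplyr::mutate(group = group, .after = "measure")
  }
  cells <- joined |>
    dplyr::group_by(.data$drug, .data$label) |>
    dplyr::group_map(~ cell_counts(.x, paste(.y$drug, .y$label, sep = "_")))
  out <- dplyr::bind_rows(cell_counts(joined, "total"), cells)
  out$measure <- factor(out$measure, levels = note_flag_cols)
  dplyr::arrange(out, .data$measure, .data$group) |>
    dplyr::mutate(measure = as.character(.data$measure))
}
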