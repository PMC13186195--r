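#' Percent change from baseline
#'
#' @param weight_kg Weight measurement(s), kg.
#' @param baseline_kg Baseline weight, kg (must be positive).
#' @return `100 * (weight_kg - baseline_kg) / baseline_kg`.
#' @examples
#' percent_change(102, 100)
#' @export
percent_change <- function(weight_kg, baseline_kg) {
  if (any(!is.finite(baseline_kg)) || any(baseline_kg <= 0)) {
    abort("baseline weight must be positive",
          class = "glp1traj_baseline_error")
  }
  100 * (weight_kg - baseline_kg) / baseline_kg
}

#' Trajectory bin of a day offset
#'
#' Bin `b` covers day offsets `[b * width, (b + 1) * width - 1]`; offsets are
#' relative to the index date (negative before it), so day 0 falls in bin 0
#' and day -1 in bin -1.
#'
#' @param day_offset Integer day offset(s) relative to the index date.
#' @param bin_width_days Bin width in days.
#' @return Integer bin index, `floor(day_offset / bin_width_days)`.
#' @examples
#' bin_of(c(-31, -30, -1, 0, 29, 30, 180))
#' @export
bin_of <- function(day_offset, bin_width_days = 30L) {
  as.integer(floor(day_offset / bin_width_days))
}

#' Per-measurement trajectory points
#'
#' One point per weight measurement inside the analysis window
#' `[-pre_window_days, followup_days]` relative to each patient's index
#' date, expressed as percent change from the patient's baseline weight;
#' measurements outside the window are dropped, and every in-window
#' measurement yields exactly one point.
#'
#' @param cohort A cohort from [build_cohort()] (its `drug` column is carried
#'   through for downstream grouping).
#' @param weights Validated weights tibble.
#' @param config A [study_config()].
#' @return A tibble: `patient_id`, `drug`, `day_offset`, `pct_change`.
#' @export
patient_trajectories <- function(cohort, weights,
                                 config = study_config()) {
  dplyr::inner_join(
    as_tibble(weights),
    dplyr::select(as_tibble(cohort), "patient_id", "drug", "index_date",
                  "baseline_weight_kg"),
    by = "patient_id"
  ) |>
    dplyr::mutate(day_offset = as.integer(.data$date - .data$index_date)) |>
    dplyr::filter(.data$day_offset >= -config$pre_window_days,
                  .data$day_offset <= config$followup_days) |>
    dplyr::mutate(pct_change = percent_change(.data$weight_kg,
                                              .data$baseline_weight_kg)) |>
    dplyr::select("patient_id", "drug", "day_offset", "pct_change")
}

#' Two-stage bin aggregation of trajectory points
#'
#' Controls for unequal measurement frequency across patients: within each
#' bin, a patient first contributes a single value (the median of their
#' in-bin percent changes); cohort-level mean and sample SD (n - 1
#' denominator) are then taken over those patient-level values, with
#' `mean +/- ci_multiplier * sd / sqrt(n)` confidence intervals. A bin with
#' one patient reports SD 0 and a degenerate interval equal to the mean;
#' empty bins are omitted.
#'
#' @param points Trajectory points from [patient_trajectories()], optionally
#'   joined with grouping columns (e.g. a regain label).
#' @param config A [study_config()].
#' @param ... Grouping columns in `points` (tidy-select), e.g. `drug, label`.
#' @return A tibble with class `"trajectory_bins"`: grouping columns,
#'   `bin_index`, `n_patients`, `mean_pct`, `sd_pct`, `ci_low_pct`,
#'   `ci_high_pct`.
#' @export
aggregate_bins <- function(points, config = study_config(), ...) {
  stage1 <- points |>
    dplyr::mutate(bin_index = bin_of(.data$day_offset,
                                     config$bin_width_days)) |>
    dplyr::group_by(dplyr::across(c(...)), .data$patient_id,
                    .data$bin_index) |>
    dplyr::summarise(patient_value = median(.data$pct_change),
                     .groups = "drop")
  out <- stage1 |>
    dplyr::group_by(dplyr::across(c(...)), .data$bin_index) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      mean_pct = mean(.data$patient_value),
      sd_pct = ifelse(dplyr::n() > 1L, sd(.data$patient_value), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low_pct = .data$mean_pct -
        config$ci_multiplier * .data$sd_pct / sqrt(.data$n_patients),
      ci_high_pct = .data$mean_pct +
        config$ci_multiplier * .data$sd_pct / sqrt(.data$n_patients)
    ) |>
    dplyr::arrange(dplyr::across(c(...)), .data$bin_index)
  class(out) <- c("trajectory_bins", class(out))
  out
}

## post-index measurements usable for classification / follow-up change:
## strictly after the index, inside the follow-up window, and never the
## baseline measurement itself (even when the baseline is dated post-index)
post_index_weights <- function(rec, weights, config) {
  off <- as.integer(weights$date - rec$index_date)
  keep <- off > 0L & off <= config$followup_days &
    weights$date != rec$baseline_date
  list(off = off[keep], kg = weights$weight_kg[keep])
}

#' Follow-up weight change (endpoint statistic)
#'
#' Percent change from the baseline (the measurement closest to the index
#' date) to the post-index measurement closest to `index + followup_days`,
#' ties resolved toward the earlier date.
#'
#' @param index_record One cohort row (list or one-row tibble with
#'   `index_date`, `baseline_weight_kg`, `baseline_date`).
#' @param weights Tibble of that patient's weight measurements.
#' @param config A [study_config()].
#' @return A single percent change.
#' @export
followup_change <- function(index_record, weights,
                            config = study_config()) {
  post <- post_index_weights(index_record, weights, config)
  if (!length(post$off)) {
    abort("patient has no post-index weight measurement",
          class = "glp1traj_followup_error")
  }
  dist <- abs(post$off - config$followup_days)
  pick <- order(dist, post$off)[1L]
  percent_change(post$kg[pick], index_record$baseline_weight_kg)
}

#' Regain classification
#'
#' A patient is labelled `"regain"` when their maximum percent change over
#' all post-index measurements within the follow-up window reaches the
#' regain threshold (boundary inclusive: exactly the threshold counts as
#' regain); otherwise `"non_regain"`. The endpoint follow-up change
#' ([followup_change()]) is carried alongside as `followup_pct`.
#'
#' @param cohort A cohort from [build_cohort()].
#' @param weights Validated weights tibble (all patients).
#' @param config A [study_config()].
#' @return A tibble: `patient_id`, `drug`, `label`, `max_post_pct`,
#'   `followup_pct`.
#' @export
classify_regain <- function(cohort, weights, config = study_config()) {
  wt_by_pt <- split(as_tibble(weights), weights$patient_id)
  co <- as_tibble(cohort)
  out <- purrr::pmap(co, function(patient_id, drug, index_date,
                                  baseline_weight_kg, baseline_date, ...) {
    rec <- list(index_date = index_date,
                baseline_weight_kg = baseline_weight_kg,
                baseline_date = baseline_date)
    wt <- wt_by_pt[[patient_id]]
    post <- post_index_weights(rec, wt, config)
    if (!length(post$off)) {
      abort(sprintf("patient %s has no post-index weight measurement",
                    patient_id),
            class = "glp1traj_followup_error")
    }
    max_post <- max(percent_change(post$kg, baseline_weight_kg))
    tibble(
      patient_id = patient_id,
      drug = drug,
      label = ifelse(max_post >= config$regain_threshold_pct,
                     "regain", "non_regain"),
      max_post_pct = max_post,
      followup_pct = followup_change(rec, wt, config)
    )
  })
  dplyr::bind_rows(out)
}
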