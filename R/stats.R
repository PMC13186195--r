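#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of freedom, with
#' the two-sided p-value from the upper tail of the chi-square distribution.
#' A Yates continuity correction is available behind a flag but is off by
#' default. A zero row or column margin (an expected count of zero) is an
#' error.
#'
#' @param x A 2x2 matrix of non-negative counts, or the count `a` when
#'   `b`, `c`, `d` are given separately (rows = outcome groups, columns =
#'   flag yes/no).
#' @param b,c,d Remaining cell counts when `x` is scalar.
#' @param correct Apply the Yates continuity correction.
#' @return An object of class `"chisq_2x2"` with elements `statistic`, `df`,
#'   `p_value`, `table`, `correct`; see [tidy()] and [glance()].
#' @examples
#' chi_square_2x2(20, 5, 10, 15)
#' @export
chi_square_2x2 <- function(x, b = NULL, c = NULL, d = NULL,
                           correct = FALSE) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    tab <- x
  } else {
    tab <- matrix(c(x, c, b, d), nrow = 2L)
  }
  if (any(!is.finite(tab)) || any(tab < 0)) {
    abort("cell counts must be non-negative numbers",
          class = "glp1traj_table_error")
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    abort("2x2 table has a zero margin; the chi-square test is undefined",
          class = "glp1traj_margin_error")
  }
  det <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
  num <- if (correct) max(abs(det) - n / 2, 0) else abs(det)
  stat <- n * num^2 / prod(c(rs, cs))
  structure(
    list(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
         table = tab, correct = correct),
    class = "chisq_2x2"
  )
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat(sprintf("Pearson chi-square (2x2%s): X-squared = %.4f, df = 1, p = %.4g\n",
              if (x$correct) ", Yates-corrected" else "",
              x$statistic, x$p_value))
  invisible(x)
}

#' @rdname chi_square_2x2
#' @param x A `"chisq_2x2"` object.
#' @param ... Unused.
#' @method tidy chisq_2x2
#' @export
tidy.chisq_2x2 <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = if (x$correct) "Pearson chi-square (Yates)"
                  else "Pearson chi-square")
}

#' @rdname chi_square_2x2
#' @method glance chisq_2x2
#' @export
glance.chisq_2x2 <- function(x, ...) tidy(x)

#' Lifestyle-counseling comparison between outcome groups
#'
#' For exercise and diet counseling separately, builds the 2x2 table of
#' outcome group (non-regain / regain) by post-index counseling
#' documentation and applies the uncorrected Pearson chi-square test,
#' reporting per-group percentages alongside. No multiplicity adjustment is
#' applied across the two comparisons.
#'
#' @param summaries Output of [summarize_notes()].
#' @param labels Output of [classify_regain()] covering every summarized
#'   patient.
#' @param correct Passed to [chi_square_2x2()].
#' @return A tibble with one row per counseling type: `counseling`,
#'   `n_non_regain`, `n_regain`, `pct_non_regain`, `pct_regain`,
#'   `statistic`, `p_value`.
#' @export
counseling_comparison <- function(summaries, labels, correct = FALSE) {
  joined <- dplyr::inner_join(as_tibble(summaries),
                              as_tibble(labels)[, c("patient_id", "label")],
                              by = "patient_id")
  if (!all(c("non_regain", "regain") %in% joined$label)) {
    abort("both outcome groups must be non-empty",
          class = "glp1traj_empty_group_error")
  }
  one <- function(flag_col, name) {
    counts <- joined |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(n = dplyr::n(), yes = sum(.data[[flag_col]]),
                       .groups = "drop")
    nr <- counts[counts$label == "non_regain", ]
    rg <- counts[counts$label == "regain", ]
    test <- chi_square_2x2(matrix(c(nr$yes, rg$yes, nr$n - nr$yes,
                                    rg$n - rg$yes), nrow = 2L),
                           correct = correct)
    tibble(counseling = name,
           n_non_regain = nr$n, n_regain = rg$n,
           pct_non_regain = 100 * nr$yes / nr$n,
           pct_regain = 100 * rg$yes / rg$n,
           statistic = test$statistic, p_value = test$p_value)
  }
  dplyr::bind_rows(one("exercise_counseling_post", "exercise"),
                   one("diet_counseling_post", "diet"))
}

#' Cohort characteristics summary per drug
#'
#' Demographic and baseline-weight summary of each drug cohort: counts and
#' percentages for sex, race, type-2 diabetes and obesity (denominator =
#' drug cohort size), mean/SD age, and mean/SD plus median/IQR of the
#' anchor weight. The weight anchor is the earliest measurement 270-365
#' days before the index date (roughly 12 months before the last
#' prescription) when one exists, otherwise the earliest measurement in the
#' analysis window.
#'
#' @param demographics Validated demographics tibble.
#' @param cohort A cohort from [build_cohort()].
#' @param weights Validated weights tibble.
#' @param config A [study_config()].
#' @return A tibble with one row per drug.
#' @export
table1_summary <- function(demographics, cohort, weights,
                           config = study_config()) {
  co <- as_tibble(cohort)
  anchor <- dplyr::inner_join(as_tibble(weights),
                              co[, c("patient_id", "index_date")],
                              by = "patient_id") |>
    dplyr::mutate(off = as.integer(.data$date - .data$index_date)) |>
    dplyr::filter(.data$off >= -config$pre_window_days,
                  .data$off <= config$followup_days) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$off, .by_group = TRUE) |>
    dplyr::summarise(anchor_weight_kg = {
      early <- .data$weight_kg[.data$off >= -config$pre_window_days &
                                 .data$off <= -270L]
      if (length(early)) early[1L] else .data$weight_kg[1L]
    }, .groups = "drop")
  joined <- co |>
    dplyr::left_join(as_tibble(demographics), by = "patient_id") |>
    dplyr::left_join(anchor, by = "patient_id")
  joined |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      n = dplyr::n(),
      female_n = sum(.data$sex == "female", na.rm = TRUE),
      female_pct = 100 * sum(.data$sex == "female", na.rm = TRUE) / dplyr::n(),
      white_pct = 100 * sum(.data$race == "white", na.rm = TRUE) / dplyr::n(),
      black_pct = 100 * sum(.data$race == "black", na.rm = TRUE) / dplyr::n(),
      other_race_pct = 100 * sum(.data$race == "other", na.rm = TRUE) /
        dplyr::n(),
      age_mean = mean(.data$age_years, na.rm = TRUE),
      age_sd = if (dplyr::n() > 1L) sd(.data$age_years, na.rm = TRUE)
               else NA_real_,
      t2d_pct = 100 * sum(.data$t2d, na.rm = TRUE) / dplyr::n(),
      obesity_pct = 100 * sum(.data$obesity, na.rm = TRUE) / dplyr::n(),
      weight_mean = mean(.data$anchor_weight_kg, na.rm = TRUE),
      weight_sd = if (dplyr::n() > 1L) sd(.data$anchor_weight_kg,
                                          na.rm = TRUE) else NA_real_,
      weight_median = median(.data$anchor_weight_kg, na.rm = TRUE),
      weight_q1 = unname(quantile(.data$anchor_weight_kg, 0.25,
                                  na.rm = TRUE, type = 2)),
      weight_q3 = unname(quantile(.data$anchor_weight_kg, 0.75,
                                  na.rm = TRUE, type = 2)),
      .groups = "drop"
    )
}

#' Histogram of follow-up weight change
#'
#' Bins the endpoint follow-up percent changes into 1-percentage-point bins
#' over [-20, 20) with open tails, and reports their mean and median. The
#' bin counts always sum to the number of patients.
#'
#' @param labels Output of [classify_regain()] (uses `followup_pct`).
#' @return An object of class `"followup_hist"`; [tidy()] returns the bin
#'   table, [glance()] the mean/median/n, and [autoplot()] draws the
#'   histogram.
#' @export
followup_histogram <- function(labels) {
  v <- labels$followup_pct
  lo <- c(-Inf, seq(-20, 20))
  hi <- c(seq(-20, 20), Inf)
  counts <- vapply(seq_along(lo), function(i) {
    sum(v >= lo[i] & v < hi[i])
  }, integer(1))
  structure(
    list(bins = tibble(bin_low = lo, bin_high = hi, count = counts),
         mean = mean(v), median = median(v), n = length(v)),
    class = "followup_hist"
  )
}

#' @export
print.followup_hist <- function(x, ...) {
  cat(sprintf("<followup_hist> n = %d, mean = %.2f%%, median = %.2f%%\n",
              x$n, x$mean, x$median))
  invisible(x)
}

#' @rdname followup_histogram
#' @param x A `"followup_hist"` object.
#' @param ... Unused.
#' @method tidy followup_hist
#' @export
tidy.followup_hist <- function(x, ...) x$bins

#' @rdname followup_histogram
#' @method glance followup_hist
#' @export
glance.followup_hist <- function(x, ...) {
  tibble(n = x$n, mean_pct = x$mean, median_pct = x$median)
}
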