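test_that("2x2 chi-square matches its closed form and known cases", {
  res <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res <- chi_square_2x2(20, 5, 10, 15)
  expect_equal(res$statistic, 25 / 3, tolerance = 1e-12)
  expect_equal(round(res$statistic, 4), 8.3333)
  expect_equal(res$p_value, 0.0039, tolerance = 1e-2)
  # row swap leaves statistic and p unchanged
  swapped <- chi_square_2x2(10, 15, 20, 5)
  expect_equal(swapped$statistic, res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(chi_square_2x2(0, 0, 5, 7), class = "glp1traj_margin_error")
  td <- tidy(res)
  expect_equal(td$p_value, res$p_value)
  expect_equal(glance(res)$statistic, res$statistic)
})

test_that("chi-square agrees with expected-counts and stats::chisq.test oracles", {
  withr::local_seed(55)
  for (rep in 1:100) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    res <- chi_square_2x2(tab)
    # independent oracle 1: sum((O - E)^2 / E) from the margins
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    # independent oracle 2: the stock Pearson test without correction
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
    # Yates-corrected variant against the stock corrected test
    refc <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
                 unname(refc$statistic), tolerance = 1e-9)
  }
})

test_that("null counseling comparisons yield uniform-ish p-values", {
  withr::local_seed(77)
  pvals <- replicate(200, {
    yes <- rbinom(2, c(150, 150), 0.25)
    chi_square_2x2(matrix(c(yes, 150 - yes), 2))$p_value
  })
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("counseling comparison reports group percentages with the test", {
  ids <- sprintf("P%03d", 1:100)
  summaries <- tibble::tibble(
    patient_id = ids, has_post_notes = TRUE,
    discontinuation_documented = FALSE, restart_or_switch_post60 = FALSE,
    outside_source = FALSE, other_aom = FALSE,
    weight_status_documented = FALSE,
    diet_counseling_post = c(rep(TRUE, 20), rep(FALSE, 80)),
    exercise_counseling_post = c(rep(TRUE, 30), rep(FALSE, 40),
                                 rep(TRUE, 5), rep(FALSE, 25)))
  labels <- tibble::tibble(patient_id = ids, drug = "semaglutide",
                           label = rep(c("non_regain", "regain"), c(70, 30)))
  cmp <- counseling_comparison(summaries, labels)
  ex <- cmp[cmp$counseling == "exercise", ]
  expect_equal(ex$pct_non_regain, 100 * 30 / 70)
  expect_equal(ex$pct_regain, 100 * 5 / 30)
  want <- chi_square_2x2(30, 40, 5, 25)
  expect_equal(ex$statistic, want$statistic)
  expect_equal(ex$p_value, want$p_value)
  # flags all false in both groups leave a zero margin
  none <- dplyr::mutate(summaries, exercise_counseling_post = FALSE,
                        diet_counseling_post = FALSE)
  expect_error(counseling_comparison(none, labels),
               class = "glp1traj_margin_error")
  # a single outcome group cannot be compared
  expect_error(
    counseling_comparison(summaries,
                          dplyr::mutate(labels, label = "non_regain")),
    class = "glp1traj_empty_group_error")
})

test_that("cohort summary percentages and quantiles recompute from the data", {
  idx <- anchor_date + 400
  cohort <- tibble::tibble(
    patient_id = c("A", "B", "C"), drug = "semaglutide", index_date = idx,
    baseline_weight_kg = 100, baseline_date = idx, n_qualifying_rx = 3L)
  demo <- tibble::tibble(
    patient_id = c("A", "B", "C"), sex = c("female", "female", "male"),
    race = c("white", "black", "white"), age_years = c(50L, 60L, 40L),
    t2d = c(TRUE, FALSE, TRUE), obesity = c(TRUE, TRUE, TRUE))
  wt <- dplyr::bind_rows(
    wt_tbl(400 - 300, 87.2, id = "A"),   # 300 d pre-index anchor
    wt_tbl(400 - 280, 100.3, id = "B"),
    wt_tbl(c(400 - 100, 400 - 50), c(117.1, 110), id = "C"))
  t1 <- table1_summary(demo, cohort, wt, study_config())
  expect_equal(t1$n, 3L)
  expect_equal(t1$female_pct, 100 * 2 / 3)
  expect_equal(t1$white_pct, 100 * 2 / 3)
  expect_equal(t1$age_mean, 50)
  expect_equal(t1$t2d_pct, 100 * 2 / 3)
  # weight anchor prefers the ~12-months-pre-index measurement, else the
  # earliest in-window one; median/quartiles of {87.2, 100.3, 117.1}
  expect_equal(t1$weight_median, 100.3)
  expect_equal(t1$weight_q1, 87.2)
  expect_equal(t1$weight_q3, 117.1)
  # degenerate one-patient cohort: percentages collapse to {0, 100}
  t1a <- table1_summary(demo[1, ], cohort[1, ], wt, study_config())
  expect_true(all(c(t1a$female_pct, t1a$white_pct, t1a$t2d_pct) == 100))
  expect_equal(t1a$black_pct, 0)
  expect_true(is.na(t1a$weight_sd))
})

test_that("follow-up histogram conserves patients and summarizes centrally", {
  labels <- tibble::tibble(patient_id = as.character(1:3),
                           drug = "semaglutide", label = "non_regain",
                           max_post_pct = 0,
                           followup_pct = c(-1, 0, 1))
  h <- followup_histogram(labels)
  expect_equal(h$mean, 0)
  expect_equal(h$median, 0)
  expect_equal(sum(tidy(h)$count), 3L)
  # open tails catch extreme values; counts always sum to n
  labels2 <- dplyr::mutate(labels, followup_pct = c(-35, 2.5, 50))
  h2 <- followup_histogram(labels2)
  expect_equal(sum(tidy(h2)$count), 3L)
  expect_equal(tidy(h2)$count[1], 1L)                   # (-Inf, -20)
  expect_equal(tidy(h2)$count[nrow(tidy(h2))], 1L)      # [20, Inf)
  expect_equal(glance(h2)$n, 3L)
})

test_that("plot methods return ggplot objects", {
  sim <- simulate_ehr(sim_config(n_patients = 30, seed = 14))
  cohort <- build_cohort(sim$prescriptions, sim$weights)
  pts <- patient_trajectories(cohort, sim$weights)
  bins <- aggregate_bins(pts, study_config(), drug)
  expect_s3_class(autoplot(bins), "ggplot")
  expect_s3_class(plot_trajectory_bins(bins), "ggplot")
  labels <- classify_regain(cohort, sim$weights)
  expect_s3_class(autoplot(followup_histogram(labels)), "ggplot")
})
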