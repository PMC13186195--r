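cfg <- study_config()

test_that("percent change and binning follow their definitions", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(102, 100), 2)
  expect_equal(percent_change(96, 120), -20)
  expect_error(percent_change(100, 0), class = "glp1traj_baseline_error")

  expect_equal(bin_of(c(0, 29, 30, -1, -30, -31, 180)),
               c(0L, 0L, 1L, -1L, -1L, -2L, 6L))
})

test_that("trajectory points cover exactly the in-window measurements", {
  cohort <- tibble::tibble(
    patient_id = "P1", drug = "semaglutide", index_date = anchor_date,
    baseline_weight_kg = 100, baseline_date = anchor_date - 10,
    n_qualifying_rx = 3L)
  wt <- wt_tbl(c(-400, -365, -10, 0, 180, 200), c(98, 104, 100, 99, 102, 103))
  pts <- patient_trajectories(cohort, wt, cfg)
  expect_equal(nrow(pts), 4L)  # -400 and +200 fall outside [-365, 180]
  expect_equal(sort(pts$day_offset), c(-365L, -10L, 0L, 180L))
  # the baseline measurement itself is a point with zero change
  expect_equal(pts$pct_change[pts$day_offset == -10L], 0)
  expect_equal(pts$pct_change[pts$day_offset == 180L], 2)
})

test_that("two-stage aggregation matches the hand-computed fixture", {
  pts <- tibble::tibble(
    patient_id = c("A", "A", "B"),
    day_offset = c(3L, 17L, 8L),
    pct_change = c(1, 3, 4))
  bins <- aggregate_bins(pts, cfg)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$n_patients, 2L)
  expect_equal(bins$mean_pct, 3)           # stage-1 medians {2, 4}
  expect_equal(bins$sd_pct, sqrt(2), tolerance = 1e-12)
  expect_equal(bins$ci_low_pct, 1.04, tolerance = 1e-9)
  expect_equal(bins$ci_high_pct, 4.96, tolerance = 1e-9)
})

test_that("aggregation is order-invariant, duplication-stable and degenerate-safe", {
  withr::local_seed(31)
  pts <- tibble::tibble(
    patient_id = sample(LETTERS[1:6], 60, replace = TRUE),
    drug = "semaglutide",
    day_offset = sample(-100:100, 60, replace = TRUE),
    pct_change = rnorm(60))
  b1 <- aggregate_bins(pts, cfg, drug)
  b2 <- aggregate_bins(pts[sample(nrow(pts)), ], cfg, drug)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  # duplicating every point leaves stage-1 medians, hence the mean, unchanged
  b3 <- aggregate_bins(dplyr::bind_rows(pts, pts), cfg, drug)
  expect_equal(b3$mean_pct, b1$mean_pct)
  expect_equal(b3$n_patients, b1$n_patients)
  # conservation: every in-window point lands in exactly one bin
  expect_equal(sum(table(bin_of(pts$day_offset))), nrow(pts))
  # single patient, single value: degenerate interval equal to the mean
  b4 <- aggregate_bins(tibble::tibble(patient_id = "Z", day_offset = 0L,
                                      pct_change = 5), cfg)
  expect_equal(b4$sd_pct, 0)
  expect_equal(b4$ci_low_pct, 5)
  expect_equal(b4$ci_high_pct, 5)
})

test_that("follow-up change uses the measurement closest to the 6-month mark", {
  rec <- list(index_date = anchor_date, baseline_weight_kg = 100,
              baseline_date = anchor_date - 5)
  expect_equal(followup_change(rec, wt_tbl(c(-5, 170), c(100, 103)), cfg), 3)
  # 179 is closer to 180 than 100 is
  rec2 <- list(index_date = anchor_date, baseline_weight_kg = 100,
               baseline_date = anchor_date)
  expect_equal(
    followup_change(rec2, wt_tbl(c(0, 100, 179), c(100, 98, 101)), cfg), 1)
  # measurements beyond the follow-up window never compete
  expect_equal(
    followup_change(rec2, wt_tbl(c(0, 178, 182), c(100, 99, 103)), cfg), -1)
  expect_error(followup_change(rec2, wt_tbl(c(0, 200), c(100, 99)), cfg),
               class = "glp1traj_followup_error")
})

test_that("regain classification is threshold-inclusive over the post-index max", {
  co <- function(base_day) tibble::tibble(
    patient_id = "P1", drug = "semaglutide", index_date = anchor_date,
    baseline_weight_kg = 100, baseline_date = anchor_date + base_day,
    n_qualifying_rx = 3L)
  lab <- classify_regain(co(-5), wt_tbl(c(-5, 50, 120), c(100, 101, 101.9)),
                         cfg)
  expect_equal(lab$label, "non_regain")
  expect_equal(lab$max_post_pct, 1.9)
  # boundary: exactly +2% counts as regain, and the max (not the endpoint)
  # drives the label
  lab <- classify_regain(co(-5), wt_tbl(c(-5, 50, 170), c(100, 102, 99)),
                         cfg)
  expect_equal(lab$label, "regain")
  expect_equal(lab$max_post_pct, 2)
  expect_equal(lab$followup_pct, -1)
  # a post-index baseline never counts as a post-index point
  lab <- classify_regain(co(10), wt_tbl(c(10, 90), c(100, 101)), cfg)
  expect_equal(lab$max_post_pct, 1)
})

test_that("classification and follow-up stats are date-shift invariant", {
  sim <- simulate_ehr(sim_config(n_patients = 40, contamination = 0,
                                 seed = 12))
  cohort <- build_cohort(sim$prescriptions, sim$weights)
  labels <- classify_regain(cohort, sim$weights)
  k <- -23L  # backward shift keeps index dates inside the study period
  wt_shift <- dplyr::mutate(sim$weights, date = date + k)
  rx_shift <- dplyr::mutate(sim$prescriptions, date = date + k)
  co_shift <- build_cohort(rx_shift, wt_shift)
  lab_shift <- classify_regain(co_shift, wt_shift)
  expect_equal(lab_shift$label, labels$label)
  expect_equal(lab_shift$max_post_pct, labels$max_post_pct)
  expect_equal(co_shift$index_date, cohort$index_date + k)
})

test_that("noise-free cohorts reproduce the latent trajectory and labels", {
  sim <- simulate_ehr(sim_config(n_patients = 150, p_regain = 0.5,
                                 weight_noise_sd_kg = 0, contamination = 0,
                                 seed = 13))
  cohort <- build_cohort(sim$prescriptions, sim$weights)
  labels <- classify_regain(cohort, sim$weights)
  tr <- truth_table(sim)
  m <- dplyr::inner_join(labels, tr, by = "patient_id")
  expect_equal(m$label.x, m$label.y)
  # cohort curve drop from bin -12 to bin -1 recovers the on-therapy loss
  pts <- patient_trajectories(cohort, sim$weights)
  bins <- aggregate_bins(pts, cfg, drug)
  for (dg in c("semaglutide", "tirzepatide")) {
    b <- bins[bins$drug == dg, ]
    drop <- b$mean_pct[b$bin_index == -12L] - b$mean_pct[b$bin_index == -1L]
    loss <- sim_config()$on_therapy_loss_pct[[dg]]
    # bin centres sit ~15 d inside each end of the year, so the observed
    # drop is slightly below the full-year loss; allow that geometry
    expect_gt(drop, loss * 330 / 365 - 1.5)
    expect_lt(drop, loss / (1 - loss / 100) + 1.5)
  }
})
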