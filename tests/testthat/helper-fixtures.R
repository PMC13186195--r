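# Fixture builders and the literal rule-text oracle used across test files.
# All fixtures are built in code; the anchor date sits inside the default
# study period so day offsets up to ~900 stay in-period.

anchor_date <- as.Date("2020-01-01")

rx_tbl <- function(days, id = "P1", ingredient = "semaglutide",
                   brand = "Ozempic", dose_mg = 1, origin = anchor_date) {
  tibble::tibble(
    patient_id = id,
    ingredient = ingredient,
    brand = brand,
    dose_mg = dose_mg,
    date = origin + days
  )
}

wt_tbl <- function(days, kg, id = "P1", origin = anchor_date) {
  tibble::tibble(patient_id = id, date = origin + days, weight_kg = kg)
}

ev_tbl <- function(days, types, id = "P1", origin = anchor_date,
                   evidence = "documented in note") {
  tibble::tibble(patient_id = id, note_date = origin + days,
                 event_type = types, evidence = evidence)
}

# Brute-force eligibility/index oracle: enumerates every window of exactly
# min_prescriptions consecutive in-period prescription dates and every
# candidate index date, checking the rules literally. Independent of the
# package's segment-based implementation.
oracle_eligibility <- function(dates, cfg = study_config()) {
  d <- sort(unique(dates))
  if (length(d) == 0L) return(list(eligible = FALSE, index = as.Date(NA)))
  dp <- d[d >= cfg$study_start & d <= cfg$study_end]
  m <- cfg$min_prescriptions
  run_end_idx <- integer(0)
  if (length(dp) >= m) {
    for (i in seq_len(length(dp) - m + 1L)) {
      j <- i + m - 1L
      win <- dp[i:j]
      if (all(diff(as.integer(win)) <= cfg$max_gap_days) &&
          as.integer(win[m] - win[1L]) <= cfg$span_days) {
        run_end_idx <- c(run_end_idx, j)
      }
    }
  }
  if (length(run_end_idx) == 0L) {
    return(list(eligible = FALSE, index = as.Date(NA)))
  }
  first_end <- dp[min(run_end_idx)]
  candidates <- as.Date(character(0))
  for (k in which(dp >= first_end)) {
    t <- dp[k]
    washout_broken <- any(d > t & d <= t + cfg$washout_days)
    if (!washout_broken) candidates <- c(candidates, t)
  }
  if (length(candidates) == 0L) {
    list(eligible = FALSE, index = as.Date(NA))
  } else {
    list(eligible = TRUE, index = min(candidates))
  }
}

# random prescription timelines for the oracle-equivalence property
random_timeline <- function() {
  n <- sample(0:8, 1)
  if (n == 0L) return(integer(0))
  span <- sample(c(300L, 900L), 1)  # mix of dense and sparse timelines
  sample(0:span, n, replace = TRUE)
}

# round-trip comparisons ignore the rejection-log attribute
as_plain_df <- function(x) {
  attr(x, "rejections") <- NULL
  as.data.frame(x)
}
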