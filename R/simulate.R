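#' Simulation configuration for the synthetic EHR generator
#'
#' Parameters of the seeded generator that emulates the data-generating
#' situation the pipeline is designed for: patients on semaglutide or
#' tirzepatide who lose weight over a pre-index year of regular
#' prescriptions, then either regain (a linear ramp reaching
#' `regain_by_day120_pct` by day 120 post-index, plateauing thereafter) or
#' hold/continue losing weight (a mild drift drawn uniformly from -2% to +1%
#' per 180 days). Visit schedules are irregular (successive gaps uniform on
#' 0.5-1.5 times `visit_interval_mean_days`), observed weights carry Gaussian
#' measurement noise, and structured note events are sampled with
#' outcome-group-specific counseling probabilities.
#'
#' Per-drug parameters are length-2 vectors named `semaglutide` and
#' `tirzepatide`; counseling probabilities are length-2 vectors named
#' `non_regain` and `regain`.
#'
#' @param n_patients Number of patients to generate.
#' @param p_tirzepatide Probability a patient is on tirzepatide.
#' @param p_regain Per-drug probability of the latent regain outcome.
#' @param on_therapy_loss_pct Per-drug percent weight lost over the pre-index
#'   year of therapy.
#' @param regain_by_day120_pct Percent regain (of baseline) reached by
#'   post-index day 120 in regainers.
#' @param weight_noise_sd_kg SD, in kg, of Gaussian measurement noise added
#'   to the latent weight.
#' @param baseline_weight_mean_kg,baseline_weight_sd_kg Per-drug mean/SD of
#'   the weight at therapy start (about 12 months before the index date).
#' @param rx_interval_days Days between successive prescriptions.
#' @param therapy_duration_days Length of the on-therapy period, in days.
#' @param visit_interval_mean_days Mean gap between weight-measurement
#'   visits, in days.
#' @param p_exercise_counseling,p_diet_counseling Per-outcome-group
#'   probabilities of a post-index counseling note event.
#' @param p_documented_discontinuation Probability of a discontinuation note
#'   event dated within 90 days of the true index date.
#' @param p_restart_switch,p_outside_source,p_other_aom,p_weight_status
#'   Probabilities of the remaining note-event types (post-index).
#' @param p_maintenance Per-drug probability that a patient's prescriptions
#'   titrate to at least the brand's maintenance dose.
#' @param contamination Fraction of patients made ineligible by construction
#'   (too few prescriptions, over-wide gaps, or no post-index weights).
#' @param date_shift_emulation Shift each patient's dates backward by a
#'   patient-specific random offset of 1-31 days, emulating
#'   de-identification date jitter that preserves within-patient intervals.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated list with class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 500L,
                       p_tirzepatide = 0.386,
                       p_regain = c(semaglutide = 0.33, tirzepatide = 0.28),
                       on_therapy_loss_pct = c(semaglutide = 7.0,
                                               tirzepatide = 11.0),
                       regain_by_day120_pct = 4.0,
                       weight_noise_sd_kg = 0.8,
                       baseline_weight_mean_kg = c(semaglutide = 103.3,
                                                   tirzepatide = 108.5),
                       baseline_weight_sd_kg = c(semaglutide = 22.6,
                                                 tirzepatide = 22.8),
                       rx_interval_days = 28L,
                       therapy_duration_days = 365L,
                       visit_interval_mean_days = 45L,
                       p_exercise_counseling = c(non_regain = 0.262,
                                                 regain = 0.147),
                       p_diet_counseling = c(non_regain = 0.223,
                                             regain = 0.235),
                       p_documented_discontinuation = 0.40,
                       p_restart_switch = 0.07,
                       p_outside_source = 0.013,
                       p_other_aom = 0.047,
                       p_weight_status = 0.49,
                       p_maintenance = c(semaglutide = 0.906,
                                         tirzepatide = 0.953),
                       contamination = 0.10,
                       date_shift_emulation = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    p_tirzepatide = p_tirzepatide,
    p_regain = drug_pair(p_regain),
    on_therapy_loss_pct = drug_pair(on_therapy_loss_pct),
    regain_by_day120_pct = regain_by_day120_pct,
    weight_noise_sd_kg = weight_noise_sd_kg,
    baseline_weight_mean_kg = drug_pair(baseline_weight_mean_kg),
    baseline_weight_sd_kg = drug_pair(baseline_weight_sd_kg),
    rx_interval_days = as.integer(rx_interval_days),
    therapy_duration_days = as.integer(therapy_duration_days),
    visit_interval_mean_days = as.integer(visit_interval_mean_days),
    p_exercise_counseling = group_pair(p_exercise_counseling),
    p_diet_counseling = group_pair(p_diet_counseling),
    p_documented_discontinuation = p_documented_discontinuation,
    p_restart_switch = p_restart_switch,
    p_outside_source = p_outside_source,
    p_other_aom = p_other_aom,
    p_weight_status = p_weight_status,
    p_maintenance = drug_pair(p_maintenance),
    contamination = contamination,
    date_shift_emulation = isTRUE(date_shift_emulation),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

drug_pair <- function(x) {
  if (length(x) == 1L) x <- c(semaglutide = unname(x), tirzepatide = unname(x))
  stopifnot(all(c("semaglutide", "tirzepatide") %in% names(x)))
  x[c("semaglutide", "tirzepatide")]
}

group_pair <- function(x) {
  if (length(x) == 1L) x <- c(non_regain = unname(x), regain = unname(x))
  stopifnot(all(c("non_regain", "regain") %in% names(x)))
  x[c("non_regain", "regain")]
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) {
    abort("n_patients must be >= 1", class = "glp1traj_config_error")
  }
  probs <- c(cfg$p_tirzepatide, cfg$p_regain, cfg$p_exercise_counseling,
             cfg$p_diet_counseling, cfg$p_documented_discontinuation,
             cfg$p_restart_switch, cfg$p_outside_source, cfg$p_other_aom,
             cfg$p_weight_status, cfg$p_maintenance, cfg$contamination)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "glp1traj_config_error")
  }
  if (cfg$weight_noise_sd_kg < 0) {
    abort("weight_noise_sd_kg must be non-negative",
          class = "glp1traj_config_error")
  }
  invisible(cfg)
}

## Table-1-style demographic frequencies (per drug: semaglutide, tirzepatide).
demo_params <- list(
  p_female = c(0.712, 0.702),
  p_white = c(0.773, 0.853),
  p_black = c(0.164, 0.081),
  age_mean = c(55.3, 55.1),
  age_sd = c(12.8, 11.8),
  p_t2d = c(0.600, 0.660),
  p_obesity = c(0.770, 0.825)
)

note_evidence <- c(
  discontinuation = "patient has stopped the medication",
  restart = "restarted weekly injections",
  switch = "switched to a different GLP-1 agent",
  outside_source = "obtaining medication from an outside provider",
  other_aom = "started phentermine for weight management",
  diet_counseling = "discussed dietary modification and portion control",
  exercise_counseling = "counseled on regular aerobic exercise",
  weight_status = "weight stable since last visit"
)

#' Generate a synthetic EHR extract
#'
#' Produces the four input tables (prescriptions, weights, demographics, note
#' events) plus a hidden per-patient truth table, deterministically given
#' `sim$seed`. Unless a patient is drawn into the contamination fraction,
#' their records satisfy the eligibility rules of `study` by construction:
#' prescriptions every `rx_interval_days` over the on-therapy period ending
#' at the true index date, no prescription afterwards, and visit gaps short
#' enough to guarantee a baseline weight near the index date and at least one
#' post-index weight.
#'
#' @param sim A [sim_config()].
#' @param study A [study_config()]; index dates are placed so the full
#'   on-therapy period falls inside the study period.
#' @return A list with class `"ehr_simulation"` and elements
#'   `prescriptions`, `weights`, `demographics`, `note_events`, `truth`
#'   (all tibbles).
#' @seealso [truth_table()], [write_simulation()]
#' @export
simulate_ehr <- function(sim = sim_config(), study = study_config()) {
  stopifnot(inherits(sim, "sim_config"), inherits(study, "study_config"))
  n_rx <- floor(sim$therapy_duration_days / sim$rx_interval_days) + 1L
  if (n_rx < study$min_prescriptions ||
      sim$rx_interval_days > study$max_gap_days) {
    abort(paste0("degenerate simulation config: the prescription schedule (",
                 "interval ", sim$rx_interval_days, " d over ",
                 sim$therapy_duration_days, " d) cannot satisfy eligibility"),
          class = "glp1traj_sim_error")
  }
  withr::with_seed(sim$seed, simulate_ehr_impl(sim, study))
}

simulate_ehr_impl <- function(sim, study) {
  n <- sim$n_patients
  id <- sprintf("P%05d", seq_len(n))

  ## patient-level draws; the drug assignment is the first use of the stream
  is_tz <- runif(n) < sim$p_tirzepatide
  di <- ifelse(is_tz, 2L, 1L)
  drug <- c("semaglutide", "tirzepatide")[di]
  regain <- unname(runif(n) < sim$p_regain[di])
  contaminated <- runif(n) < sim$contamination
  cont_mode <- sample(c("few_rx", "wide_gap", "no_followup_weight"), n,
                      replace = TRUE)
  cont_mode[!contaminated] <- NA_character_

  period_days <- as.integer(study$study_end - study$study_start)
  index_offset <- sim$therapy_duration_days +
    floor(runif(n) * (period_days - sim$therapy_duration_days + 1))
  index_date <- study$study_start + index_offset

  brand <- character(n)
  brand[!is_tz] <- sample(c("Ozempic", "Wegovy", "Rybelsus"), sum(!is_tz),
                          replace = TRUE, prob = c(0.50, 0.35, 0.15))
  brand[is_tz] <- sample(c("Mounjaro", "Zepbound"), sum(is_tz),
                         replace = TRUE)
  maintainer <- unname(runif(n) < sim$p_maintenance[di])

  w0 <- unname(pmin(pmax(rnorm(n, sim$baseline_weight_mean_kg[di],
                             sim$baseline_weight_sd_kg[di]), 45), 350))
  w_index <- unname(w0 * (1 - sim$on_therapy_loss_pct[di] / 100))
  slope_nr <- runif(n, -2, 1)  # non-regain drift, pct per 180 d
  shift <- if (sim$date_shift_emulation) sample(1:31, n, replace = TRUE)
           else integer(n)

  dur <- sim$therapy_duration_days
  thr <- maintenance_thresholds()
  rx_list <- vector("list", n)
  wt_list <- vector("list", n)
  nt_list <- vector("list", n)

  for (i in seq_len(n)) {
    ## prescriptions (day offsets relative to the true index date)
    mode <- cont_mode[i]
    if (identical(mode, "few_rx")) {
      rx_off <- c(-sim$rx_interval_days, 0L)
    } else if (identical(mode, "wide_gap")) {
      wide <- study$max_gap_days + 30L
      rx_off <- c(-2L * wide, -wide, 0L)
    } else {
      rx_off <- -rev(seq(0L, dur, by = sim$rx_interval_days))
    }
    t0 <- thr[[brand[i]]]
    dose <- rep(t0 / 2, length(rx_off))
    if (maintainer[i]) {
      esc <- rx_off >= rx_off[min(length(rx_off),
                                  ceiling(length(rx_off) / 3) + 1L)]
      dose[esc] <- t0
    }
    rx_list[[i]] <- list(off = rx_off, dose = dose)

    ## visit schedule and observed weights
    gaps <- round(runif(40, 0.5, 1.5) * sim$visit_interval_mean_days)
    first <- -dur + round(runif(1, 0, 0.5 * sim$visit_interval_mean_days))
    v <- first + cumsum(c(0, gaps))
    v <- v[v <= study$followup_days]
    if (identical(mode, "no_followup_weight")) v <- v[v <= 0]
    pre <- v <= 0
    latent <- numeric(length(v))
    latent[pre] <- w0[i] + (w_index[i] - w0[i]) * (v[pre] + dur) / dur
    post <- v[!pre]
    if (regain[i]) {
      latent[!pre] <- w_index[i] *
        (1 + sim$regain_by_day120_pct / 100 * pmin(post, 120) / 120)
    } else {
      latent[!pre] <- w_index[i] * (1 + slope_nr[i] / 100 * post / 180)
    }
    obs <- latent + rnorm(length(v), 0, sim$weight_noise_sd_kg)
    wt_list[[i]] <- list(off = v, kg = obs)

    ## note events
    ev_type <- character(0)
    ev_off <- integer(0)
    grp <- if (regain[i]) "regain" else "non_regain"
    if (runif(1) < sim$p_documented_discontinuation) {
      ev_type <- c(ev_type, "discontinuation")
      ev_off <- c(ev_off, sample(-90:90, 1))
    }
    if (runif(1) < sim$p_exercise_counseling[[grp]]) {
      ev_type <- c(ev_type, "exercise_counseling")
      ev_off <- c(ev_off, sample(1:365, 1))
    }
    if (runif(1) < sim$p_diet_counseling[[grp]]) {
      ev_type <- c(ev_type, "diet_counseling")
      ev_off <- c(ev_off, sample(1:365, 1))
    }
    if (runif(1) < sim$p_restart_switch) {
      ev_type <- c(ev_type, sample(c("restart", "switch"), 1))
      ev_off <- c(ev_off, sample(61:365, 1))
    }
    if (runif(1) < sim$p_outside_source) {
      ev_type <- c(ev_type, "outside_source")
      ev_off <- c(ev_off, sample(1:365, 1))
    }
    if (runif(1) < sim$p_other_aom) {
      ev_type <- c(ev_type, "other_aom")
      ev_off <- c(ev_off, sample(1:365, 1))
    }
    if (runif(1) < sim$p_weight_status) {
      ev_type <- c(ev_type, "weight_status")
      ev_off <- c(ev_off, sample(1:365, 1))
    }
    nt_list[[i]] <- list(type = ev_type, off = ev_off)
  }

  rx_len <- vapply(rx_list, function(x) length(x$off), 1L)
  prescriptions <- tibble(
    patient_id = rep(id, rx_len),
    ingredient = rep(drug, rx_len),
    brand = rep(brand, rx_len),
    dose_mg = unlist(lapply(rx_list, `[[`, "dose")),
    date = rep(index_date - shift, rx_len) +
      unlist(lapply(rx_list, `[[`, "off"))
  )
  wt_len <- vapply(wt_list, function(x) length(x$off), 1L)
  weights <- tibble(
    patient_id = rep(id, wt_len),
    date = rep(index_date - shift, wt_len) +
      unlist(lapply(wt_list, `[[`, "off")),
    weight_kg = unlist(lapply(wt_list, `[[`, "kg"))
  )
  sex <- ifelse(runif(n) < demo_params$p_female[di], "female", "male")
  u_race <- runif(n)
  race <- ifelse(u_race < demo_params$p_white[di], "white",
                 ifelse(u_race < demo_params$p_white[di] +
                          demo_params$p_black[di], "black", "other"))
  demographics <- tibble(
    patient_id = id,
    sex = sex,
    race = race,
    age_years = pmin(pmax(as.integer(round(
      rnorm(n, demo_params$age_mean[di], demo_params$age_sd[di]))), 18L), 89L),
    t2d = runif(n) < demo_params$p_t2d[di],
    obesity = runif(n) < demo_params$p_obesity[di]
  )
  nt_len <- vapply(nt_list, function(x) length(x$off), 1L)
  types <- unlist(lapply(nt_list, `[[`, "type"))
  note_events <- tibble(
    patient_id = rep(id, nt_len),
    note_date = rep(index_date - shift, nt_len) +
      unlist(lapply(nt_list, `[[`, "off")),
    event_type = types,
    evidence = unname(note_evidence[types])
  )
  if (length(types) == 0) {
    note_events$event_type <- character(0)
    note_events$evidence <- character(0)
  }
  truth <- tibble(
    patient_id = id,
    drug = drug,
    brand = brand,
    index_date = index_date - shift,
    label = ifelse(regain, "regain", "non_regain"),
    maintainer = maintainer,
    eligible = !contaminated,
    contamination_mode = cont_mode,
    weight_at_index_kg = w_index
  )
  structure(
    list(prescriptions = prescriptions, weights = weights,
         demographics = demographics, note_events = note_events,
         truth = truth),
    class = "ehr_simulation"
  )
}

#' Ground-truth table of a simulation
#'
#' One row per generated patient: drug, brand, true index date, latent
#' regain label, maintenance-titration flag, eligibility flag and (for
#' contaminated patients) the ineligibility mechanism.
#'
#' @param x An `"ehr_simulation"` from [simulate_ehr()].
#' @return A tibble.
#' @export
truth_table <- function(x) {
  stopifnot(inherits(x, "ehr_simulation"))
  x$truth
}

#' Write a simulation to a directory of CSV files
#'
#' Writes `prescriptions.csv`, `weights.csv`, `demographics.csv`,
#' `note_events.csv` and `truth.csv` under `dir`.
#'
#' @param x An `"ehr_simulation"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(x, dir) {
  stopifnot(inherits(x, "ehr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ehr_table(x$prescriptions, file.path(dir, "prescriptions.csv"),
                  "prescriptions")
  write_ehr_table(x$weights, file.path(dir, "weights.csv"), "weights")
  write_ehr_table(x$demographics, file.path(dir, "demographics.csv"),
                  "demographics")
  write_ehr_table(x$note_events, file.path(dir, "note_events.csv"),
                  "note_events")
  readr::write_csv(x$truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.ehr_simulation <- function(x, ...) {
  cat(sprintf(
    "<ehr_simulation> %d patients: %d prescriptions, %d weights, %d note events\n",
    nrow(x$truth), nrow(x$prescriptions), nrow(x$weights),
    nrow(x$note_events)))
  invisible(x)
}
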