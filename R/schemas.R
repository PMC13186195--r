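## Record schemas shared by the readers, writers and the generator.
## One record type per CSV file; comma-delimited, UTF-8, ISO 8601 dates.

glp1_ingredients <- c("semaglutide", "tirzepatide")
glp1_brands <- c("Ozempic", "Wegovy", "Rybelsus", "Mounjaro", "Zepbound",
                 "unknown")
brand_ingredient <- c(
  Ozempic = "semaglutide", Wegovy = "semaglutide", Rybelsus = "semaglutide",
  Mounjaro = "tirzepatide", Zepbound = "tirzepatide"
)
note_event_types <- c(
  "discontinuation", "restart", "switch", "outside_source", "other_aom",
  "diet_counseling", "exercise_counseling", "weight_status"
)

ehr_schemas <- list(
  prescriptions = list(
    columns = c("patient_id", "ingredient", "brand", "dose_mg", "date"),
    date_cols = "date"
  ),
  weights = list(
    columns = c("patient_id", "date", "weight_kg"),
    date_cols = "date"
  ),
  demographics = list(
    columns = c("patient_id", "sex", "race", "age_years", "t2d", "obesity"),
    date_cols = character(0)
  ),
  note_events = list(
    columns = c("patient_id", "note_date", "event_type", "evidence"),
    date_cols = "note_date"
  )
)

#' Read a validated EHR extract table
#'
#' Reads one of the four comma-delimited input tables (`prescriptions`,
#' `weights`, `demographics`, `note_events`), parses ISO 8601 dates, and
#' validates every row against the schema's invariants. Validation is total:
#' each input row is either returned or recorded in the rejection log attached
#' as the `"rejections"` attribute (a tibble of row numbers and reasons),
#' never silently dropped.
#'
#' Row-level invariants: prescriptions must name a study ingredient, a brand
#' consistent with it (or `"unknown"`), and a dose in (0, 50] mg when present;
#' weights must fall within plausibility bounds; ages must be at most 120;
#' note events must carry a non-empty evidence excerpt.
#'
#' @param path Path to a CSV file whose header names the schema's fields.
#' @param schema One of `"prescriptions"`, `"weights"`, `"demographics"`,
#'   `"note_events"`.
#' @param weight_bounds_kg Plausibility bounds for weight measurements, in kg.
#' @param quiet Suppress the rejection-count message.
#' @return A tibble of valid records with a `"rejections"` attribute; see
#'   [rejected_rows()].
#' @seealso [write_ehr_table()]
#' @export
read_ehr_table <- function(path,
                           schema = c("prescriptions", "weights",
                                      "demographics", "note_events"),
                           weight_bounds_kg = c(20, 400),
                           quiet = FALSE) {
  schema <- match.arg(schema)
  sch <- ehr_schemas[[schema]]
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path),
          class = "glp1traj_file_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  missing_cols <- setdiff(sch$columns, names(x))
  if (length(missing_cols)) {
    abort(sprintf("file %s lacks required column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "glp1traj_schema_error")
  }
  x <- x[sch$columns]
  for (dc in sch$date_cols) {
    parsed <- as.Date(x[[dc]], format = "%Y-%m-%d")
    bad <- !is.na(x[[dc]]) & is.na(parsed)
    if (any(bad)) {
      abort(sprintf("column '%s' of %s has %d unparseable date(s); ISO 8601 (YYYY-MM-DD) expected",
                    dc, path, sum(bad)),
            class = "glp1traj_date_error")
    }
    x[[dc]] <- parsed
  }
  coerced <- coerce_ehr_types(x, schema)
  reasons <- validate_ehr_rows(coerced, schema, weight_bounds_kg)
  keep <- is.na(reasons)
  rejections <- tibble(row = which(!keep), reason = reasons[!keep])
  out <- coerced[keep, , drop = FALSE]
  if (!quiet && nrow(rejections) > 0) {
    message(sprintf("read_ehr_table: rejected %d of %d row(s) from %s",
                    nrow(rejections), nrow(coerced), path))
  }
  attr(out, "rejections") <- rejections
  out
}

coerce_ehr_types <- function(x, schema) {
  switch(schema,
    prescriptions = dplyr::mutate(x,
      brand = dplyr::coalesce(.data$brand, "unknown"),
      dose_mg = suppressWarnings(as.numeric(.data$dose_mg))),
    weights = dplyr::mutate(x,
      weight_kg = suppressWarnings(as.numeric(.data$weight_kg))),
    demographics = dplyr::mutate(x,
      age_years = suppressWarnings(as.integer(.data$age_years)),
      t2d = parse_flag(.data$t2d),
      obesity = parse_flag(.data$obesity)),
    note_events = x
  )
}

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

## Returns NA for valid rows, else the first failing reason.
validate_ehr_rows <- function(x, schema, weight_bounds_kg) {
  n <- nrow(x)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  no_id <- is.na(x$patient_id) | x$patient_id == ""
  flag(no_id, "missing_patient_id")
  if (schema == "prescriptions") {
    flag(is.na(x$date), "missing_date")
    flag(!x$ingredient %in% glp1_ingredients, "unknown_ingredient")
    flag(!x$brand %in% glp1_brands, "unknown_brand_value")
    known <- x$brand %in% names(brand_ingredient)
    flag(known & brand_ingredient[x$brand] != x$ingredient,
         "brand_ingredient_mismatch")
    flag(!is.na(x$dose_mg) & (x$dose_mg <= 0 | x$dose_mg > 50),
         "dose_out_of_range")
  } else if (schema == "weights") {
    flag(is.na(x$date), "missing_date")
    flag(is.na(x$weight_kg) | x$weight_kg < weight_bounds_kg[1] |
           x$weight_kg > weight_bounds_kg[2], "weight_out_of_range")
  } else if (schema == "demographics") {
    flag(!x$sex %in% c("female", "male"), "unknown_sex")
    flag(!x$race %in% c("white", "black", "other"), "unknown_race")
    flag(is.na(x$age_years) | x$age_years < 0 | x$age_years > 120,
         "age_out_of_range")
    flag(is.na(x$t2d) | is.na(x$obesity), "missing_flag")
  } else if (schema == "note_events") {
    flag(is.na(x$note_date), "missing_date")
    flag(!x$event_type %in% note_event_types, "unknown_event_type")
    flag(is.na(x$evidence) | trimws(x$evidence) == "", "empty_evidence")
  }
  reason
}

#' Rejection log of a validated table
#'
#' @param x A tibble returned by [read_ehr_table()].
#' @return A tibble with columns `row` and `reason` (empty when no row was
#'   rejected).
#' @export
rejected_rows <- function(x) {
  rej <- attr(x, "rejections", exact = TRUE)
  if (is.null(rej)) tibble(row = integer(0), reason = character(0)) else rej
}

#' Write an EHR extract table
#'
#' Writes records as comma-delimited UTF-8 with ISO 8601 dates, so that
#' `read_ehr_table(write_ehr_table(x, path), schema)` reproduces `x`
#' field-for-field. An empty input yields a header-only file.
#'
#' @param x A tibble of records of one schema.
#' @param path Output path.
#' @inheritParams read_ehr_table
#' @return `path`, invisibly.
#' @export
write_ehr_table <- function(x, path,
                            schema = c("prescriptions", "weights",
                                       "demographics", "note_events")) {
  schema <- match.arg(schema)
  sch <- ehr_schemas[[schema]]
  missing_cols <- setdiff(sch$columns, names(x))
  if (length(missing_cols)) {
    abort(sprintf("records lack required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "glp1traj_schema_error")
  }
  out <- as_tibble(x)[sch$columns]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
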