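#' Write a cohort to CSV (with an optional generator-truth sidecar)
#'
#' The measurement table is written with header columns `patient_id`,
#' `date` (ISO-8601), `hb_mmol_l`, `gender`, `birth_year`. For synthetic
#' cohorts the generating truth is serialized alongside as
#' `<path-sans-ext>_truth.csv` (per-measurement noiseless value joined with
#' the patient-level setpoint and drift label) so a written cohort remains
#' usable for recovery checks.
#'
#' @param cohort An `hb_cohort`.
#' @param path Output CSV path.
#' @param truth Write the truth sidecar when available? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth = TRUE) {
  stopifnot(inherits(cohort, "hb_cohort"))
  m <- cohort$measurements
  readr::write_csv(
    tibble::tibble(
      patient_id = m$patient_id,
      date = format(m$date, "%Y-%m-%d"),
      hb_mmol_l = m$value,
      gender = m$gender,
      birth_year = m$birth_year
    ),
    path
  )
  if (truth && !is.null(cohort$truth)) {
    side <- dplyr::left_join(
      cohort$truth$trajectory,
      cohort$truth$patients[, c("patient_id", "setpoint", "drift")],
      by = "patient_id"
    )
    readr::write_csv(side, truth_sidecar_path(path))
  }
  invisible(path)
}

truth_sidecar_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0("_truth.csv")
}

#' Read a cohort from CSV
#'
#' Validates the schema (required columns `patient_id`, `date`, `hb_mmol_l`,
#' `gender`, `birth_year`), parses ISO-8601 dates, and rejects
#' non-positive Hb values with the offending line number. Duplicate
#' (patient, date) rows are accepted here; same-day deduplication is a
#' preprocessing decision, not a parsing one.
#'
#' @param path CSV path as produced by [write_cohort()].
#' @param truth Also load the `_truth.csv` sidecar when present?
#' @return An `hb_cohort` with provenance `"file"`.
#' @export
read_cohort <- function(path, truth = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "date", "hb_mmol_l", "gender", "birth_year")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$hb_mmol_l))
  bad <- which(is.na(value))
  if (length(bad) > 0) {
    stop(sprintf("cohort parse error at line %d: hb_mmol_l '%s' is not numeric",
                 bad[1] + 1L, raw$hb_mmol_l[bad[1]]), call. = FALSE)
  }
  nonpos <- which(value <= 0)
  if (length(nonpos) > 0) {
    stop(sprintf("cohort schema error at line %d: hb_mmol_l must be > 0 (got %s)",
                 nonpos[1] + 1L, raw$hb_mmol_l[nonpos[1]]), call. = FALSE)
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date))
  if (length(bad_date) > 0) {
    stop(sprintf("cohort parse error at line %d: date '%s' is not ISO-8601",
                 bad_date[1] + 1L, raw$date[bad_date[1]]), call. = FALSE)
  }
  birth_year <- suppressWarnings(as.integer(raw$birth_year))
  if (anyNA(birth_year)) {
    i <- which(is.na(birth_year))[1]
    stop(sprintf("cohort parse error at line %d: birth_year '%s' is not an integer",
                 i + 1L, raw$birth_year[i]), call. = FALSE)
  }
  measurements <- tibble::tibble(
    patient_id = raw$patient_id, date = date, value = value,
    gender = raw$gender, birth_year = birth_year
  )
  truth_obj <- NULL
  side <- truth_sidecar_path(path)
  if (truth && file.exists(side)) {
    traj <- readr::read_csv(side, col_types = readr::cols(
      patient_id = readr::col_character(), date = readr::col_date(),
      drift = readr::col_logical(), .default = readr::col_double()
    ))
    truth_obj <- list(
      patients = dplyr::distinct(
        traj[, intersect(c("patient_id", "setpoint", "drift"), names(traj))]
      ),
      trajectory = traj[, intersect(c("patient_id", "date", "noiseless",
                                      "trend", "drift_term"), names(traj))]
    )
  }
  new_cohort(measurements, provenance = "file", truth = truth_obj)
}
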