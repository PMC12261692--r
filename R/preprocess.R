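#' Inclusion-filter rules
#'
#' Whole-patient inclusion criteria applied after same-day deduplication:
#' minimum age at first measurement, Hb range bounds (any value outside the
#' bounds excludes the entire patient), and bounds on the total number of
#' measurements. Defaults match the primary analysis: Hb within
#' \[6, 16.5\] mmol/L, 3 to 100 measurements, age 16 and above. Gender-specific
#' Hb bounds (as used for the refined gender-stratified subsets, e.g.
#' 6--12 mmol/L for females and 7--13 for males) are supported by passing
#' named vectors `c(female = ..., male = ...)`.
#'
#' @param min_age Minimum age (years) at the first measurement.
#' @param hb_min,hb_max Hb bounds in mmol/L; scalars or named
#'   `c(female=, male=)` vectors.
#' @param min_measurements,max_measurements Bounds on the per-patient count.
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(min_age = 16, hb_min = 6, hb_max = 16.5,
                         min_measurements = 3L, max_measurements = 100L) {
  rules <- list(
    min_age = min_age, hb_min = hb_min, hb_max = hb_max,
    min_measurements = as.integer(min_measurements),
    max_measurements = as.integer(max_measurements)
  )
  if (any(bound_for(rules$hb_min, c("female", "male")) >=
          bound_for(rules$hb_max, c("female", "male")))) {
    stop_config("hb_min/hb_max", "must satisfy hb_min < hb_max")
  }
  if (rules$min_measurements < 1L) {
    stop_config("min_measurements", "must be >= 1")
  }
  if (rules$max_measurements < rules$min_measurements) {
    stop_config("max_measurements", "must be >= min_measurements")
  }
  structure(rules, class = "filter_rules")
}

# Resolve a scalar-or-per-gender bound for a gender vector.
bound_for <- function(bound, gender) {
  if (length(bound) == 1L && is.null(names(bound))) {
    rep_len(unname(bound), length(gender))
  } else {
    if (!all(c("female", "male") %in% names(bound))) {
      stop_config("hb bounds", "per-gender bounds need names 'female' and 'male'")
    }
    unname(bound[gender])
  }
}

#' Remove duplicate same-day measurements
#'
#' Keeps at most one measurement per (patient, date). The survivor is the
#' first record in file order — a deterministic, order-stable tie-break.
#' Removal counts are appended to the cohort's attrition log.
#'
#' @param cohort An `hb_cohort`.
#' @return The deduplicated `hb_cohort`.
#' @export
deduplicate_same_day <- function(cohort) {
  stopifnot(inherits(cohort, "hb_cohort"))
  before <- cohort$measurements
  keep <- !duplicated(before[, c("patient_id", "date")])
  cohort$measurements <- before[keep, ]
  log_attrition(cohort, "deduplicate_same_day", before)
}

#' Apply whole-patient inclusion filters
#'
#' Excludes entire patients when (1) age at the first retained measurement is
#' below `min_age`, (2) any Hb value falls outside the configured range, or
#' (3) the total measurement count falls outside
#' \[`min_measurements`, `max_measurements`\]. One attrition stage is logged
#' per rule, in that order.
#'
#' @param cohort A deduplicated `hb_cohort`.
#' @param rules A [filter_rules()] object.
#' @return The filtered `hb_cohort`; its `attrition` field carries the
#'   per-stage log.
#' @export
apply_inclusion_filters <- function(cohort, rules = filter_rules()) {
  stopifnot(inherits(cohort, "hb_cohort"), inherits(rules, "filter_rules"))
  m <- cohort$measurements

  first <- m |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  too_young <- first$patient_id[
    age_at_date(first$birth_year, first$date) < rules$min_age
  ]
  before <- cohort$measurements
  cohort$measurements <- m[!m$patient_id %in% too_young, ]
  cohort <- log_attrition(cohort, "min_age", before)

  m <- cohort$measurements
  lo <- bound_for(rules$hb_min, m$gender)
  hi <- bound_for(rules$hb_max, m$gender)
  out_of_range <- unique(m$patient_id[m$value < lo | m$value > hi])
  before <- cohort$measurements
  cohort$measurements <- m[!m$patient_id %in% out_of_range, ]
  cohort <- log_attrition(cohort, "hb_range", before)

  m <- cohort$measurements
  counts <- table(m$patient_id)
  bad_count <- names(counts)[counts < rules$min_measurements |
                             counts > rules$max_measurements]
  before <- cohort$measurements
  cohort$measurements <- m[!m$patient_id %in% bad_count, ]
  cohort <- log_attrition(cohort, "measurement_count", before)

  if (!is.null(cohort$truth)) {
    keep <- unique(cohort$measurements$patient_id)
    cohort$truth$patients <-
      cohort$truth$patients[cohort$truth$patients$patient_id %in% keep, ]
    cohort$truth$trajectory <-
      cohort$truth$trajectory[cohort$truth$trajectory$patient_id %in% keep, ]
  }
  cohort
}

# Decimal age at a calendar date given a birth year (mid-year convention).
age_at_date <- function(birth_year, date) {
  (as.numeric(format(date, "%Y")) +
     (as.POSIXlt(date)$yday) / 365.25) - (birth_year + 0.5)
}

#' Build model rows with no-lookahead features
#'
#' Per patient (sorted by date) derives the regression features: the
#' response `y` (the row's Hb value), `time_since_first` in days from the
#' patient's first retained measurement, `past_mean` — by default the
#' expanding mean of all *strictly earlier* values, so a row never sees its
#' own or any future value — `age` at the measurement date, and `gender`.
#' The patient's first row has no history and is dropped. Patients with
#' fewer than two measurements cannot form any row and are skipped with a
#' warning.
#'
#' @param cohort A filtered, deduplicated `hb_cohort`.
#' @param past_mean_mode `"expanding_strict"` (default): per-row mean of
#'   strictly earlier values. `"train_constant"`: an alternative reading in
#'   which every row of a patient carries the constant mean of that
#'   patient's pre-holdout (all-but-last) values.
#' @return A tibble with columns `patient_id`, `date`, `y`,
#'   `time_since_first`, `past_mean`, `age`, `gender`.
#' @export
build_model_rows <- function(cohort,
                             past_mean_mode = c("expanding_strict", "train_constant")) {
  stopifnot(inherits(cohort, "hb_cohort"))
  past_mean_mode <- match.arg(past_mean_mode)
  m <- cohort$measurements |>
    dplyr::arrange(.data$patient_id, .data$date)

  singletons <- names(which(table(m$patient_id) < 2))
  if (length(singletons) > 0) {
    warning(length(singletons),
            " patient(s) with < 2 measurements skipped (no usable history)")
    m <- m[!m$patient_id %in% singletons, ]
  }
  if (nrow(m) == 0) {
    return(tibble::tibble(
      patient_id = character(), date = as.Date(character()), y = numeric(),
      time_since_first = numeric(), past_mean = numeric(), age = numeric(),
      gender = character()
    ))
  }

  m |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      time_since_first = as.numeric(.data$date - .data$date[1L]),
      past_mean = if (past_mean_mode == "expanding_strict") {
        dplyr::lag(cumsum(.data$value)) / dplyr::lag(seq_along(.data$value))
      } else {
        mean(.data$value[-dplyr::n()])
      },
      .row = dplyr::row_number()
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.row > 1L) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      date = .data$date,
      y = .data$value,
      time_since_first = .data$time_since_first,
      past_mean = .data$past_mean,
      age = age_at_date(.data$birth_year, .data$date),
      gender = .data$gender
    )
}

#' Hold-out-last train/test split
#'
#' Per patient the most recent model row becomes the single test row; all
#' earlier rows are training rows. Patients who would contribute no
#' training row (their series produced a single model row) are excluded
#' from both partitions.
#'
#' @param rows A model-row tibble from [build_model_rows()].
#' @return An object of class `hb_split`: `list(train=, test=, excluded=)`,
#'   with exactly one test row per retained patient.
#' @export
holdout_split <- function(rows) {
  if (nrow(rows) == 0) {
    warning("empty model-row input: returning empty split")
    return(structure(list(train = rows, test = rows, excluded = character()),
                     class = "hb_split"))
  }
  counts <- table(rows$patient_id)
  excluded <- names(counts)[counts < 2]
  rows <- rows[!rows$patient_id %in% excluded, ]
  if (length(excluded) > 0) {
    message(length(excluded),
            " patient(s) excluded from the split (no training row)")
  }
  is_last <- rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(.last = .data$date == max(.data$date)) |>
    dplyr::pull(.data$.last)
  structure(
    list(train = rows[!is_last, ], test = rows[is_last, ], excluded = excluded),
    class = "hb_split"
  )
}

#' @export
print.hb_split <- function(x, ...) {
  cat(sprintf("<hb_split> %d train rows, %d test rows (%d patients)\n",
              nrow(x$train), nrow(x$test),
              dplyr::n_distinct(x$test$patient_id)))
  invisible(x)
}
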