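#' Personalized reference range from a patient's history
#'
#' An individualized "normal" range built from the patient's own historical
#' Hb values: `mean(history) +/- k * sd(history)`, with the sample
#' (n - 1 denominator) standard deviation. The caller guarantees that the
#' history excludes the held-out most recent measurement. A constant history
#' yields a zero-width range rather than an error.
#'
#' @param history Numeric vector of historical Hb values (mmol/L), at least
#'   two values.
#' @param k SD multiplier (> 0); the primary analysis uses 2.5, the
#'   population-diagnostics convention is 2.
#' @param patient_id Optional identifier carried into the result.
#' @return A one-row tibble of class `personal_range` with columns
#'   `patient_id`, `n_history`, `mean`, `sd`, `k`, `low`, `high`.
#' @export
#' @examples
#' compute_personal_range(c(7.5, 8.0, 8.5), k = 2.5)
compute_personal_range <- function(history, k = 2.5, patient_id = NA_character_) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  history <- as.numeric(history)
  if (length(history) < 2L || anyNA(history)) {
    stop("history must contain at least 2 non-missing values (sd undefined otherwise)",
         call. = FALSE)
  }
  m <- mean(history)
  s <- sd(history)
  structure(
    tibble::tibble(
      patient_id = patient_id, n_history = length(history),
      mean = m, sd = s, k = k, low = m - k * s, high = m + k * s
    ),
    class = c("personal_range", "tbl_df", "tbl", "data.frame")
  )
}

#' Personalized ranges for every patient in a cohort
#'
#' Computes [compute_personal_range()] per patient from all measurements
#' except the most recent one (the held-out test point). Patients with fewer
#' than three measurements (fewer than two historical values) are dropped.
#'
#' @param cohort A preprocessed `hb_cohort`.
#' @param k SD multiplier.
#' @return A tibble with one `personal_range` row per patient.
#' @export
personal_ranges <- function(cohort, k = 2.5) {
  stopifnot(inherits(cohort, "hb_cohort"))
  cohort$measurements |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      history_mean = mean(.data$value[-dplyr::n()]),
      history_sd = sd(.data$value[-dplyr::n()]),
      n_history = dplyr::n() - 1L,
      .groups = "drop"
    ) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      n_history = .data$n_history,
      mean = .data$history_mean,
      sd = .data$history_sd,
      k = k,
      low = .data$history_mean - k * .data$history_sd,
      high = .data$history_mean + k * .data$history_sd
    )
}

#' Classify a value against a personalized range
#'
#' Boundaries are inclusive: a value exactly on `low` or `high` is
#' `"normal"` (ties do not flag). Vectorized over paired values and ranges.
#'
#' @param value Hb value(s) in mmol/L.
#' @param range A `personal_range` row or a range table whose rows pair with
#'   `value`.
#' @return Character vector over `{"normal", "out_of_normal"}`.
#' @export
classify_value <- function(value, range) {
  stopifnot(is.numeric(value), all(c("low", "high") %in% names(range)))
  if (nrow(range) != length(value) && nrow(range) != 1L) {
    stop("range must have one row, or one row per value", call. = FALSE)
  }
  ifelse(value >= range$low & value <= range$high, "normal", "out_of_normal")
}
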