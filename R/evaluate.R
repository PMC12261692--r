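#' Mean squared prediction error
#'
#' `sum((y_hat - y)^2) / N` over paired held-out predictions and actuals.
#'
#' @param predictions,actuals Equal-length numeric vectors, paired by
#'   patient.
#' @return A single nonnegative number (squared mmol/L).
#' @export
mspe <- function(predictions, actuals) {
  if (length(predictions) != length(actuals)) {
    stop("predictions and actuals must have equal length", call. = FALSE)
  }
  if (length(predictions) < 1) stop("need at least one pair", call. = FALSE)
  mean((predictions - actuals)^2)
}

#' Coverage fractions for held-out predictions
#'
#' Three agreement fractions: predictions within an absolute error
#' threshold `delta` of the actual value; actual values inside their
#' prediction interval; and actual values within two pooled SDs of the
#' pooled mean (the population-range analogue).
#'
#' @param predictions A [predict_with_ci()] tibble (`y_hat`, `ci_low`,
#'   `ci_high`).
#' @param actuals Actual held-out values, paired with `predictions` rows.
#' @param delta Acceptable absolute error in mmol/L (default 0.5).
#' @param pooled_sd Pooled SD used for the two-SD band; defaults to
#'   `sd(actuals)`.
#' @return A list: `frac_within_delta`, `ci_coverage`, `frac_within_2sd`.
#' @export
coverage_fractions <- function(predictions, actuals, delta = 0.5,
                               pooled_sd = sd(actuals)) {
  if (nrow(predictions) != length(actuals)) {
    stop("predictions and actuals must have equal length", call. = FALSE)
  }
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  list(
    frac_within_delta = mean(abs(predictions$y_hat - actuals) <= delta),
    ci_coverage = mean(actuals >= predictions$ci_low &
                       actuals <= predictions$ci_high),
    frac_within_2sd = mean(abs(actuals - mean(actuals)) <= 2 * pooled_sd)
  )
}

#' Confusion matrix over normal / out-of-normal classifications
#'
#' Counts with the positive class "within personal normal bounds": TP both
#' labels normal; FN actual normal but predicted out; FP actual out but
#' predicted normal; TN both out.
#'
#' @param predicted_class,actual_class Character vectors over
#'   `{"normal", "out_of_normal"}`, paired by patient.
#' @return A list of class `hb_confusion` with integer fields
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_from_classifications <- function(predicted_class, actual_class) {
  if (length(predicted_class) != length(actual_class)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  valid <- c("normal", "out_of_normal")
  bad <- setdiff(unique(c(predicted_class, actual_class)), valid)
  if (length(bad) > 0) {
    stop("label(s) outside {normal, out_of_normal}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  confusion_matrix(
    tp = sum(actual_class == "normal" & predicted_class == "normal"),
    fn = sum(actual_class == "normal" & predicted_class == "out_of_normal"),
    fp = sum(actual_class == "out_of_normal" & predicted_class == "normal"),
    tn = sum(actual_class == "out_of_normal" & predicted_class == "out_of_normal")
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn Nonnegative integer counts; positive class is
#'   "within personal normal bounds".
#' @return A list of class `hb_confusion`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(setNames(as.integer(round(counts)), names(counts))),
            class = "hb_confusion")
}

#' @export
print.hb_confusion <- function(x, ...) {
  cat("<hb_confusion> (positive class = normal)\n")
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Exact textbook formulas: prevalence (TP+FN)/total, accuracy
#' (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN), false positive
#' rate FP/(FP+TN), F1 = 2PR/(P+R). A metric whose denominator is zero is
#' reported as `NA` rather than raising. Specificity and negative
#' predictive value are included as the complementary clinical view.
#'
#' @param m An `hb_confusion`.
#' @param k Optional SD multiplier the matrix was computed at (carried
#'   through for sweep tables).
#' @return A one-row tibble (proportions in \[0, 1\], plus `n` and `k`).
#' @export
metrics_from_matrix <- function(m, k = NA_real_) {
  stopifnot(inherits(m, "hb_confusion"))
  total <- m$tp + m$fn + m$fp + m$tn
  if (total <= 0) stop("confusion matrix is empty", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(m$tp, m$tp + m$fp)
  recall <- safe_div(m$tp, m$tp + m$fn)
  tibble::tibble(
    prevalence = (m$tp + m$fn) / total,
    accuracy = (m$tp + m$tn) / total,
    precision = precision,
    recall = recall,
    fpr = safe_div(m$fp, m$fp + m$tn),
    f1 = if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_,
    specificity = safe_div(m$tn, m$fp + m$tn),
    npv = safe_div(m$tn, m$tn + m$fn),
    n = total,
    k = k
  )
}

#' SD-threshold robustness sweep
#'
#' For each multiplier in `k_grid`, recomputes every patient's personalized
#' range at that k, classifies the model's point prediction and the actual
#' held-out value against it, builds the confusion matrix, and reports the
#' metric row. Only patients present in all three inputs are evaluated.
#'
#' @param cohort Preprocessed `hb_cohort` supplying the per-patient
#'   histories (all measurements except the held-out last).
#' @param test Test rows from [holdout_split()] (`patient_id`, `y`).
#' @param predictions [predict_with_ci()] output paired to `test`.
#' @param k_grid Strictly increasing positive multipliers.
#' @return A tibble with one metric row per k, plus the raw counts.
#' @export
threshold_sweep <- function(cohort, test, predictions,
                            k_grid = c(1.5, 1.75, 2, 2.25, 2.5)) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty", call. = FALSE)
  if (any(k_grid <= 0) || any(diff(k_grid) <= 0)) {
    stop("k_grid must be strictly increasing and positive", call. = FALSE)
  }
  dplyr::bind_rows(lapply(k_grid, function(k) {
    ranges <- personal_ranges(cohort, k = k)
    eval_tbl <- test |>
      dplyr::select("patient_id", actual = "y") |>
      dplyr::inner_join(
        dplyr::select(predictions, "patient_id", "y_hat"), by = "patient_id"
      ) |>
      dplyr::inner_join(ranges, by = "patient_id")
    m <- confusion_from_classifications(
      predicted_class = classify_value(eval_tbl$y_hat, eval_tbl),
      actual_class = classify_value(eval_tbl$actual, eval_tbl)
    )
    dplyr::bind_cols(
      metrics_from_matrix(m, k = k),
      tibble::tibble(tp = m$tp, fn = m$fn, fp = m$fp, tn = m$tn)
    )
  }))
}

#' Intraclass correlation (one-way random-effects ANOVA estimator)
#'
#' Proportion of total variance attributable to between-patient
#' differences, from the one-way ANOVA mean squares with the
#' unbalanced-design group-size correction
#' `n0 = (N - sum(n_i^2)/N) / (groups - 1)`:
#' `sigma_b^2 = (MSB - MSW) / n0`, ICC = `sigma_b^2 / (sigma_b^2 + MSW)`,
#' truncated at 0 when the between mean square falls below the within.
#'
#' @param values Numeric vector of observations (e.g. Hb values, or model
#'   residuals for the post-model ICC).
#' @param group Grouping vector (patient IDs) paired with `values`.
#' @return ICC estimate in \[0, 1\].
#' @export
icc <- function(values, group) {
  if (length(values) != length(group)) {
    stop("values and group must have equal length", call. = FALSE)
  }
  group <- as.character(group)
  ni <- table(group)
  ni <- ni[ni >= 2]
  if (length(ni) < 2) {
    stop("need at least 2 patients with at least 2 values each", call. = FALSE)
  }
  keep <- group %in% names(ni)
  values <- values[keep]
  group <- group[keep]
  ni <- as.numeric(table(group))
  k <- length(ni)
  n_total <- sum(ni)
  grand <- mean(values)
  group_means <- tapply(values, group, mean)
  ssb <- sum(ni * (group_means - grand)^2)
  ssw <- sum((values - group_means[group])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n_total - k)
  n0 <- (n_total - sum(ni^2) / n_total) / (k - 1)
  sigma_b2 <- max((msb - msw) / n0, 0)
  sigma_b2 / (sigma_b2 + msw)
}
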