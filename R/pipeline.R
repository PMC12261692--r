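#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations: synthetic generator (or an input
#' CSV), inclusion filters, model specification, the SD multiplier and
#' sweep grid for personalized ranges, interval level, error threshold, and
#' the global seed. The single seed is fanned out deterministically to
#' per-stage child seeds, so results are reproducible from
#' (configuration, seed) alone.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when `input_csv` is
#'   given.
#' @param input_csv Optional path to a cohort CSV ([read_cohort()] format);
#'   overrides `synthetic`.
#' @param filters A [filter_rules()].
#' @param model A [model_spec()].
#' @param past_mean_mode Passed to [build_model_rows()].
#' @param k_default SD multiplier for the primary personalized ranges.
#' @param k_grid Multipliers for the robustness sweep.
#' @param ci_level Prediction-interval level.
#' @param interval `"prediction"` or `"mean"` (see [predict_with_ci()]).
#' @param delta Acceptable absolute error (mmol/L) for the error-threshold
#'   fraction.
#' @param output_dir Optional directory for artifact files.
#' @param seed Global integer seed.
#' @return A list of class `hb_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_csv = NULL,
                            filters = filter_rules(),
                            model = model_spec(),
                            past_mean_mode = "expanding_strict",
                            k_default = 2.5,
                            k_grid = c(1.5, 1.75, 2, 2.25, 2.5),
                            ci_level = 0.95,
                            interval = "prediction",
                            delta = 0.5,
                            output_dir = NULL,
                            seed = 1L) {
  if (is.null(input_csv) && is.null(synthetic)) {
    stop_config("synthetic/input_csv", "one source of data is required")
  }
  assert_scalar_number(k_default, "k_default", lower = 1e-12)
  assert_scalar_number(ci_level, "ci_level", 1e-12, 1 - 1e-12)
  assert_scalar_number(delta, "delta", lower = 1e-12)
  structure(
    list(synthetic = synthetic, input_csv = input_csv, filters = filters,
         model = model, past_mean_mode = past_mean_mode,
         k_default = k_default, k_grid = k_grid, ci_level = ci_level,
         interval = interval, delta = delta, output_dir = output_dir,
         seed = as.integer(seed)),
    class = "hb_pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML with optional nested sections `synthetic`, `filters`
#' and `model` whose keys are the arguments of [synthetic_config()],
#' [filter_rules()] and [model_spec()]; top-level keys are the remaining
#' [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return An `hb_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$synthetic)) {
    args$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  if (!is.null(raw$filters)) args$filters <- do.call(filter_rules, raw$filters)
  if (!is.null(raw$model)) {
    if (!is.null(raw$model$smooth_terms)) {
      raw$model$smooth_terms <- unlist(raw$model$smooth_terms)
    }
    args$model <- do.call(model_spec, raw$model)
  }
  top <- raw[setdiff(names(raw), c("synthetic", "filters", "model"))]
  if (!is.null(top$k_grid)) top$k_grid <- as.numeric(unlist(top$k_grid))
  do.call(pipeline_config, c(args, top))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, deduplicates same-day records, applies
#' the inclusion filters, builds no-lookahead model rows, performs the
#' hold-out-last split, fits the additive model, predicts every held-out
#' measurement with intervals, constructs personalized ranges from each
#' patient's pre-holdout history, classifies predicted and actual values
#' against them, and computes the evaluation quantities (MSPE,
#' error-threshold and interval coverage, confusion metrics at
#' `k_default`, the SD-threshold sweep, and pre-/post-model ICC). With an
#' `output_dir` the intermediate tables and a run report are written as
#' CSV/text artifacts.
#'
#' @param config An [pipeline_config()] object.
#' @return An object of class `hb_evaluation` (see Details in the package
#'   vignette): evaluation scalars, the metric tables, and the fitted model.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hb_pipeline_config"))

  cohort <- if (!is.null(config$input_csv)) {
    read_cohort(config$input_csv)
  } else {
    syn <- config$synthetic
    syn$seed <- child_seed(config$seed, "generate")
    generate_cohort(syn)
  }

  cohort <- deduplicate_same_day(cohort)
  cohort <- apply_inclusion_filters(cohort, config$filters)
  if (nrow(cohort$measurements) == 0) {
    stop("pipeline stage 'preprocess': no measurements survive the filters",
         call. = FALSE)
  }

  rows <- build_model_rows(cohort, past_mean_mode = config$past_mean_mode)
  split <- holdout_split(rows)
  if (nrow(split$train) == 0) {
    stop("pipeline stage 'split': no training rows", call. = FALSE)
  }

  model <- fit_additive_model(split$train, config$model)
  predictions <- predict_with_ci(model, split$test,
                                 ci_level = config$ci_level,
                                 interval = config$interval)

  ranges <- personal_ranges(cohort, k = config$k_default)
  eval_tbl <- split$test |>
    dplyr::select("patient_id", actual = "y") |>
    dplyr::inner_join(predictions, by = "patient_id") |>
    dplyr::inner_join(ranges, by = "patient_id")

  confusion <- confusion_from_classifications(
    predicted_class = classify_value(eval_tbl$y_hat, eval_tbl),
    actual_class = classify_value(eval_tbl$actual, eval_tbl)
  )
  metrics <- metrics_from_matrix(confusion, k = config$k_default)
  sweep <- threshold_sweep(cohort, split$test, predictions,
                           k_grid = config$k_grid)

  pooled_sd <- sd(split$train$y)
  cov_frac <- coverage_fractions(
    dplyr::select(eval_tbl, "y_hat", "ci_low", "ci_high"),
    eval_tbl$actual, delta = config$delta, pooled_sd = pooled_sd
  )

  icc_pre <- icc(split$train$y, split$train$patient_id)
  icc_post <- icc(residuals(model$fit), split$train$patient_id)

  result <- structure(
    list(
      mspe = mspe(eval_tbl$y_hat, eval_tbl$actual),
      rmse = sqrt(mspe(eval_tbl$y_hat, eval_tbl$actual)),
      frac_within_delta = cov_frac$frac_within_delta,
      ci_coverage = cov_frac$ci_coverage,
      frac_within_2sd = cov_frac$frac_within_2sd,
      confusion = confusion,
      metrics = metrics,
      sweep = sweep,
      icc_pre = icc_pre,
      icc_post = icc_post,
      deviance_explained = model$deviance_explained,
      n_train = nrow(split$train),
      n_test = nrow(split$test),
      attrition = cohort$attrition,
      predictions = predictions,
      ranges = ranges,
      eval_table = eval_tbl,
      model = model,
      cohort = cohort,
      split = split,
      config = config
    ),
    class = "hb_evaluation"
  )

  if (!is.null(config$output_dir)) write_pipeline_artifacts(result, config)
  result
}

#' @export
print.hb_evaluation <- function(x, ...) {
  cat("<hb_evaluation>\n")
  cat(sprintf("  patients evaluated: %d (train rows %d)\n", x$n_test, x$n_train))
  cat(sprintf("  MSPE %.4f mmol/L^2 (RMSE %.4f), |err| <= %.2f: %.2f%%, PI coverage %.2f%%\n",
              x$mspe, x$rmse, x$config$delta, 100 * x$frac_within_delta,
              100 * x$ci_coverage))
  cat(sprintf("  ICC pre %.3f, post %.3f; deviance explained %.1f%%\n",
              x$icc_pre, x$icc_post, 100 * x$deviance_explained))
  m <- x$metrics
  cat(sprintf(
    "  at k = %.2f: accuracy %.2f%%, precision %.2f%%, recall %.2f%%, FPR %.2f%%\n",
    m$k, 100 * m$accuracy, 100 * m$precision, 100 * m$recall, 100 * m$fpr
  ))
  invisible(x)
}

write_pipeline_artifacts <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  write_cohort(result$cohort, p("cohort.csv"))
  model_rows <- dplyr::bind_rows(
    dplyr::mutate(result$split$train, partition = "train"),
    dplyr::mutate(result$split$test, partition = "test")
  )
  readr::write_csv(model_rows, p("model_rows.csv"))
  readr::write_csv(result$attrition, p("attrition.csv"))
  readr::write_csv(model_summary_table(result$model), p("model_summary.csv"))
  readr::write_csv(result$ranges, p("ranges.csv"))
  readr::write_csv(result$metrics, p("metrics.csv"))
  readr::write_csv(result$sweep, p("sweep.csv"))
  readr::write_csv(result$predictions, p("predictions.csv"))
  saveRDS(result$model, p("model.rds"))
  writeLines(run_report_lines(result), p("report.txt"))
  invisible(config$output_dir)
}

# Plain-text run report: confusion counts first, then metric/formula/value.
run_report_lines <- function(result) {
  cm <- result$confusion
  m <- result$metrics
  pct <- function(x) ifelse(is.na(x), "undefined", sprintf("%.2f%%", 100 * x))
  c(
    sprintf("Personalized-range evaluation at k = %.2f (positive class = normal)", m$k),
    "",
    "Confusion matrix",
    sprintf("  TP (both normal):            %d", cm$tp),
    sprintf("  FN (actual normal, pred out): %d", cm$fn),
    sprintf("  FP (actual out, pred normal): %d", cm$fp),
    sprintf("  TN (both out-of-normal):      %d", cm$tn),
    sprintf("  Total:                        %d", m$n),
    "",
    "Metrics",
    sprintf("  prevalence: (TP+FN)/Total: %s", pct(m$prevalence)),
    sprintf("  accuracy: (TP+TN)/Total: %s", pct(m$accuracy)),
    sprintf("  precision: TP/(TP+FP): %s", pct(m$precision)),
    sprintf("  recall: TP/(TP+FN): %s", pct(m$recall)),
    sprintf("  FPR: FP/(FP+TN): %s", pct(m$fpr)),
    sprintf("  F1: 2*P*R/(P+R): %s", pct(m$f1)),
    sprintf("  specificity: TN/(FP+TN): %s", pct(m$specificity)),
    "",
    sprintf("MSPE: %.4f mmol/L^2 (RMSE %.4f mmol/L)", result$mspe, result$rmse),
    sprintf("Predictions within +/- %.2f mmol/L: %s",
            result$config$delta, pct(result$frac_within_delta)),
    sprintf("Interval coverage (level %.2f): %s",
            result$config$ci_level, pct(result$ci_coverage)),
    sprintf("ICC pre-model: %.4f, post-model residuals: %.4f",
            result$icc_pre, result$icc_post)
  )
}

#' Compare a simple and a sophisticated model on a patient subset
#'
#' Draws a random subset of patients, fits the default ("simple")
#' specification and a sophisticated variant with gender-specific
#' past-mean smooths on the same training rows, and reports AIC, BIC and
#' held-out MSPE for both. A lower AIC for the sophisticated model combined
#' with a worse held-out MSPE is the overfitting signature this comparison
#' is designed to expose.
#'
#' @param config An [pipeline_config()].
#' @param n_patients Subset size (default 100).
#' @return A two-row tibble: `model`, `aic`, `bic`, `mspe`.
#' @export
run_subset_comparison <- function(config, n_patients = 100) {
  stopifnot(inherits(config, "hb_pipeline_config"))
  syn <- config$synthetic
  syn$seed <- child_seed(config$seed, "generate")
  cohort <- generate_cohort(syn) |>
    deduplicate_same_day() |>
    apply_inclusion_filters(config$filters)

  ids <- unique(cohort$measurements$patient_id)
  if (n_patients > length(ids)) {
    stop("subset larger than the filtered cohort (", length(ids), " patients)",
         call. = FALSE)
  }
  keep <- with_seed(child_seed(config$seed, "subset"),
                    sample(ids, n_patients))
  cohort$measurements <- cohort$measurements[
    cohort$measurements$patient_id %in% keep, ]

  split <- holdout_split(build_model_rows(cohort, config$past_mean_mode))
  simple_spec <- config$model
  simple_spec$by_gender_smooths <- FALSE
  soph_spec <- config$model
  soph_spec$by_gender_smooths <- TRUE

  fit_one <- function(label, spec) {
    fit <- fit_additive_model(split$train, spec)
    preds <- predict_with_ci(fit, split$test, ci_level = config$ci_level)
    joined <- dplyr::inner_join(
      dplyr::select(split$test, "patient_id", actual = "y"),
      dplyr::select(preds, "patient_id", "y_hat"), by = "patient_id"
    )
    tibble::tibble(model = label, aic = fit$aic, bic = fit$bic,
                   mspe = mspe(joined$y_hat, joined$actual))
  }
  dplyr::bind_rows(
    fit_one("simple", simple_spec),
    fit_one("sophisticated", soph_spec)
  )
}
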