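#' Specification of the additive Hb model
#'
#' Declares the structure fitted by [fit_additive_model()]: penalized cubic
#' regression spline smooths for the named covariates, a parametric gender
#' effect, and a ridge-penalized random intercept per patient whose penalty
#' is selected together with the smoothing parameters. Smoothness is chosen
#' by REML (default) or GCV.
#'
#' @param smooth_terms Named integer vector mapping smooth covariates to
#'   basis dimensions; every dimension must be at least 3. The default puts
#'   dimension-10 smooths on age, strictly-past average Hb, and time since
#'   the first measurement.
#' @param parametric_terms Character vector of linear/factor terms.
#' @param random_intercept Include the per-patient random intercept?
#' @param by_gender_smooths Replace the single `past_mean` smooth by
#'   gender-specific smooths (the "sophisticated" model variant).
#' @param smoothing_selection `"REML"` or `"GCV"`.
#' @param engine `"gam"` (default) or `"bam"` (the large-data fitter).
#' @return A list of class `hb_model_spec`.
#' @export
model_spec <- function(smooth_terms = c(age = 10L, past_mean = 10L,
                                        time_since_first = 10L),
                       parametric_terms = "gender",
                       random_intercept = TRUE,
                       by_gender_smooths = FALSE,
                       smoothing_selection = c("REML", "GCV"),
                       engine = c("gam", "bam")) {
  smoothing_selection <- match.arg(smoothing_selection)
  engine <- match.arg(engine)
  if (length(smooth_terms) > 0) {
    if (is.null(names(smooth_terms)) || any(!nzchar(names(smooth_terms)))) {
      stop_config("smooth_terms", "must be a named vector (covariate = basis dimension)")
    }
    if (any(smooth_terms < 3)) {
      stop_config("smooth_terms", "every basis dimension must be >= 3")
    }
  }
  structure(
    list(smooth_terms = smooth_terms, parametric_terms = parametric_terms,
         random_intercept = random_intercept,
         by_gender_smooths = by_gender_smooths,
         smoothing_selection = smoothing_selection, engine = engine),
    class = "hb_model_spec"
  )
}

# Assemble the mgcv formula, shrinking a smooth's basis dimension when the
# covariate has too few distinct values and demoting it to a linear term
# when even a minimal spline basis cannot be supported.
build_gam_formula <- function(spec, data) {
  terms <- spec$parametric_terms
  for (cov in names(spec$smooth_terms)) {
    n_distinct <- length(unique(data[[cov]]))
    k <- min(spec$smooth_terms[[cov]], n_distinct - 1L)
    if (n_distinct < 4L) {
      terms <- c(terms, cov)
    } else if (spec$by_gender_smooths && cov == "past_mean") {
      terms <- c(terms, sprintf("s(%s, by = gender, k = %d, bs = 'cr')", cov, k))
    } else {
      terms <- c(terms, sprintf("s(%s, k = %d, bs = 'cr')", cov, k))
    }
  }
  if (spec$random_intercept) {
    terms <- c(terms, "s(patient_id, bs = 're')")
  }
  as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Fit the penalized-spline additive model
#'
#' Penalized least squares with automatic smoothness selection via
#' `mgcv`: each smooth carries a roughness penalty whose weight is chosen by
#' the configured criterion, smooths are centered (sum-to-zero over the
#' observed covariate values) for identifiability, and the patient random
#' intercept is realized as a ridge-penalized offset block whose variance is
#' selected with the other penalties. Reported per-term effective degrees of
#' freedom (edf) are trace-based.
#'
#' @param train Model-row tibble (see [build_model_rows()]).
#' @param spec An [model_spec()] object.
#' @param sp Optional fixed smoothing-parameter vector (one per penalty,
#'   in formula order), bypassing automatic selection; mainly useful for
#'   studying the penalty limit.
#' @return An object of class `hb_additive_model` wrapping the fit, with a
#'   Table-style summary (`$smooth_table`, `$parametric_table`), information
#'   criteria, residual scale, and the per-patient offsets.
#' @export
fit_additive_model <- function(train, spec = model_spec(), sp = NULL) {
  stopifnot(inherits(spec, "hb_model_spec"))
  if (nrow(train) == 0) stop("training data is empty", call. = FALSE)
  needed <- c("y", names(spec$smooth_terms), spec$parametric_terms,
              if (spec$random_intercept) "patient_id")
  missing <- setdiff(needed, names(train))
  if (length(missing) > 0) {
    stop("training data lacks covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cov in names(spec$smooth_terms)) {
    if (length(unique(train[[cov]])) < 2) {
      stop("smooth covariate '", cov, "' has fewer than 2 distinct values",
           call. = FALSE)
    }
  }
  d <- as.data.frame(train)
  d$gender <- factor(d$gender)
  if (spec$random_intercept) d$patient_id <- factor(d$patient_id)
  fml <- build_gam_formula(spec, d)
  degenerate <- is.null(sp) && var(d$y) < 1e-14
  if (degenerate) {
    # constant response: smoothness selection has nothing to optimize (REML
    # degenerates at zero residual variance); pin every penalty high so the
    # fit collapses to the intercept
    setup <- mgcv::gam(fml, data = d, fit = FALSE)
    sp <- rep(1e8, length(setup$S))
  }
  fit <- if (degenerate) {
    mgcv::gam(fml, data = d, sp = sp)
  } else if (spec$engine == "bam") {
    # bam's fast-REML with covariate discretization: the standard choice for
    # large cohorts; GCV is not available in this mode.
    mgcv::bam(fml, data = d, method = "fREML", discrete = TRUE, sp = sp)
  } else {
    mgcv::gam(fml, data = d, sp = sp,
              method = if (spec$smoothing_selection == "REML") "REML" else "GCV.Cp")
  }
  new_additive_model(fit, spec, d)
}

new_additive_model <- function(fit, spec, data) {
  sm <- summary(fit)
  smooth_table <- if (length(fit$smooth) > 0) {
    tibble::tibble(
      term = rownames(sm$s.table),
      edf = sm$s.table[, "edf"],
      ref_df = sm$s.table[, "Ref.df"],
      f_value = sm$s.table[, "F"],
      p_value = sm$s.table[, "p-value"]
    )
  } else {
    tibble::tibble(term = character(), edf = numeric(), ref_df = numeric(),
                   f_value = numeric(), p_value = numeric())
  }
  parametric_table <- tibble::tibble(
    term = rownames(sm$p.table),
    estimate = sm$p.table[, "Estimate"],
    std_error = sm$p.table[, "Std. Error"],
    t_value = sm$p.table[, "t value"],
    p_value = sm$p.table[, "Pr(>|t|)"]
  )
  re_label <- grep("patient_id", smooth_table$term, value = TRUE)
  offsets <- NULL
  if (spec$random_intercept && length(re_label) == 1) {
    ix <- fit$smooth[[which(vapply(fit$smooth, function(s) s$label, "") == re_label)]]
    cf <- coef(fit)[ix$first.para:ix$last.para]
    offsets <- tibble::tibble(patient_id = levels(data$patient_id), offset = unname(cf))
  }
  structure(
    list(
      fit = fit, spec = spec,
      beta0 = unname(coef(fit)[1]),
      parametric_table = parametric_table,
      smooth_table = smooth_table,
      random_intercepts = offsets,
      scale = fit$sig2,
      aic = stats::AIC(fit), bic = stats::BIC(fit),
      deviance = stats::deviance(fit),
      deviance_explained = sm$dev.expl,
      edf_total = sum(fit$edf),
      # alternative (2*tr(A) - tr(A'A)) effective df, the form appropriate
      # for test statistics; falls back to edf when the fitter omits it
      edf1_total = if (!is.null(fit$edf1)) sum(fit$edf1) else sum(fit$edf),
      df_residual = fit$df.residual,
      n_train = nrow(data),
      train_patients = if (spec$random_intercept) levels(data$patient_id) else character(),
      gender_levels = levels(data$gender)
    ),
    class = "hb_additive_model"
  )
}

#' @export
print.hb_additive_model <- function(x, ...) {
  cat(sprintf(
    "<hb_additive_model> n = %d, intercept = %.3f mmol/L, scale = %.4f\n",
    x$n_train, x$beta0, x$scale
  ))
  cat(sprintf("  AIC %.1f, BIC %.1f, deviance explained %.1f%%\n",
              x$aic, x$bic, 100 * x$deviance_explained))
  if (nrow(x$smooth_table) > 0) {
    cat("  smooth terms (edf):",
        paste(sprintf("%s %.2f", x$smooth_table$term, x$smooth_table$edf),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Table-style model summary
#'
#' Parametric coefficients (estimate, SE, t, p) stacked above the smooth
#' terms (edf, reference df, F, p) — the layout used to report additive
#' model fits.
#'
#' @param model An `hb_additive_model`.
#' @return A tibble with a `part` column (`"parametric"` / `"smooth"`).
#' @export
model_summary_table <- function(model) {
  stopifnot(inherits(model, "hb_additive_model"))
  dplyr::bind_rows(
    dplyr::mutate(model$parametric_table, part = "parametric"),
    dplyr::mutate(model$smooth_table, part = "smooth")
  ) |>
    dplyr::relocate("part")
}

# Prepare newdata for prediction; returns list(data, unseen) where unseen
# marks rows whose patient was not in training (offset contribution 0).
prediction_frame <- function(model, rows) {
  d <- as.data.frame(rows)
  vars <- setdiff(all.vars(stats::formula(model$fit)), "y")
  missing <- setdiff(vars, names(d))
  if (length(missing) > 0) {
    stop("prediction rows lack covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- d[, vars, drop = FALSE]
  if ("gender" %in% vars) {
    bad_gender <- setdiff(unique(as.character(d$gender)), model$gender_levels)
    if (length(bad_gender) > 0) {
      stop("unseen gender level(s): ", paste(bad_gender, collapse = ", "),
           call. = FALSE)
    }
    d$gender <- factor(d$gender, levels = model$gender_levels)
  }
  unseen <- rep(FALSE, nrow(d))
  if (model$spec$random_intercept) {
    unseen <- !as.character(d$patient_id) %in% model$train_patients
    if (any(unseen)) {
      warning(sum(unseen),
              " row(s) for patients unseen in training: random-intercept offset set to 0")
    }
    shown <- as.character(d$patient_id)
    shown[unseen] <- model$train_patients[1]
    d$patient_id <- factor(shown, levels = model$train_patients)
  }
  list(data = d, unseen = unseen)
}

#' Predict held-out values with intervals
#'
#' Point predictions from the fitted additive predictor (the patient offset
#' is included for patients seen in training and zero otherwise) with
#' symmetric normal intervals. The default is a prediction interval for a
#' new observation — standard error of the fitted mean combined with the
#' residual variance — because the evaluation asks whether the *next
#' measurement* falls inside; `interval = "mean"` gives the narrower
#' confidence interval for the conditional mean.
#'
#' @param model An `hb_additive_model`.
#' @param rows Model rows carrying all covariates.
#' @param ci_level Interval level in (0, 1), default 0.95.
#' @param interval `"prediction"` (default) or `"mean"`.
#' @return A tibble: `patient_id`, `y_hat`, `ci_low`, `ci_high`, `ci_level`.
#' @export
predict_with_ci <- function(model, rows, ci_level = 0.95,
                            interval = c("prediction", "mean")) {
  stopifnot(inherits(model, "hb_additive_model"))
  interval <- match.arg(interval)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  }
  pf <- prediction_frame(model, rows)
  d <- pf$data
  re_lab <- grep("patient_id", model$smooth_table$term, value = TRUE)
  pred <- function(sub, exclude = NULL) {
    predict(model$fit, newdata = sub, se.fit = TRUE, exclude = exclude,
            newdata.guaranteed = TRUE)
  }
  y_hat <- se <- numeric(nrow(d))
  if (any(!pf$unseen)) {
    p <- pred(d[!pf$unseen, , drop = FALSE])
    y_hat[!pf$unseen] <- as.numeric(p$fit)
    se[!pf$unseen] <- as.numeric(p$se.fit)
  }
  if (any(pf$unseen)) {
    p <- pred(d[pf$unseen, , drop = FALSE], exclude = re_lab)
    y_hat[pf$unseen] <- as.numeric(p$fit)
    se[pf$unseen] <- as.numeric(p$se.fit)
  }
  z <- qnorm((1 + ci_level) / 2)
  half <- z * if (interval == "prediction") sqrt(se^2 + model$scale) else se
  tibble::tibble(
    patient_id = as.character(rows$patient_id),
    y_hat = y_hat, ci_low = y_hat - half, ci_high = y_hat + half,
    ci_level = ci_level
  )
}

#' Per-term contributions of the additive predictor
#'
#' Decomposes predictions into the intercept plus one column per model term
#' (centered smooth contributions, parametric contributions, patient
#' offset), so that additivity — prediction equals the row sum plus
#' intercept — can be asserted directly.
#'
#' @param model An `hb_additive_model`.
#' @param rows Model rows.
#' @return A list with `intercept` and a numeric matrix `terms`.
#' @export
term_contributions <- function(model, rows) {
  pf <- prediction_frame(model, rows)
  tm <- predict(model$fit, newdata = pf$data, type = "terms",
                newdata.guaranteed = TRUE)
  if (any(pf$unseen)) {
    re_col <- grep("patient_id", colnames(tm))
    if (length(re_col) == 1) tm[pf$unseen, re_col] <- 0
  }
  list(intercept = model$beta0, terms = tm)
}

#' Fit the linear mixed-effects baseline
#'
#' Same response and covariates as the additive model, but every covariate
#' effect is linear; the patient random intercept is retained (as the same
#' ridge-penalized block, so both models share one estimation machinery and
#' one reporting shape). Linear terms are reported in the smooth slots with
#' edf = 1.
#'
#' @param train Model-row tibble.
#' @param covariates Linear covariates, default age, past-mean Hb and time
#'   since first measurement.
#' @param random_intercept Include the per-patient intercept? Default `TRUE`.
#' @param smoothing_selection Criterion for the random-intercept penalty.
#' @return An `hb_additive_model` whose smooth table holds the (possible)
#'   random-effect term; linear covariates appear in the parametric table.
#' @export
fit_mixed_baseline <- function(train,
                               covariates = c("age", "past_mean", "time_since_first"),
                               random_intercept = TRUE,
                               smoothing_selection = "REML") {
  spec <- model_spec(
    smooth_terms = setNames(integer(0), character(0)),
    parametric_terms = c("gender", covariates),
    random_intercept = random_intercept,
    smoothing_selection = smoothing_selection
  )
  fit_additive_model(train, spec)
}

#' Compare nested additive models by analysis of deviance
#'
#' Reports AIC/BIC differences and an approximate F test for the terms
#' present in the full but not the reduced model, based on the drop in
#' residual deviance over the difference in total effective degrees of
#' freedom, scaled by the full model's residual variance. Used in
#' particular to test whether the patient random intercept improves on the
#' model without it.
#'
#' @param full,reduced Fitted `hb_additive_model`s on the same data;
#'   `reduced`'s terms must be a subset of `full`'s.
#' @return A one-row tibble: `delta_aic`, `delta_bic` (reduced minus full),
#'   `deviance_full`, `deviance_reduced`, `df`, `f_value`, `p_value`. When
#'   the extra terms carry less than half an effective parameter (the
#'   penalty has shrunk them out), `p_value` is `NA`: the comparison holds
#'   no evidence and the F approximation degenerates there.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "hb_additive_model"),
            inherits(reduced, "hb_additive_model"))
  term_set <- function(m) {
    c(m$smooth_table$term, setdiff(m$parametric_table$term, "(Intercept)"))
  }
  extra <- setdiff(term_set(reduced), term_set(full))
  if (length(extra) > 0) {
    stop("models are not nested: reduced has term(s) absent from full: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (full$n_train != reduced$n_train) {
    stop("models were fitted to different numbers of rows", call. = FALSE)
  }
  df <- full$edf1_total - reduced$edf1_total
  dev_drop <- reduced$deviance - full$deviance
  # An F test needs a non-vanishing numerator df: as df -> 0 the deviance
  # drop of the extra penalized term is ~ df * sigma^2, so F -> 1 while the
  # reference distribution degenerates toward 0 and any such F looks
  # extreme. Below half an effective parameter the comparison carries no
  # evidence and the p-value is reported as undefined.
  if (df > 0.5) {
    f_value <- (dev_drop / df) / full$scale
    p_value <- pf(f_value, df, full$df_residual, lower.tail = FALSE)
  } else {
    f_value <- if (df > 0) (dev_drop / df) / full$scale else 0
    p_value <- NA_real_
  }
  tibble::tibble(
    delta_aic = reduced$aic - full$aic,
    delta_bic = reduced$bic - full$bic,
    deviance_full = full$deviance,
    deviance_reduced = reduced$deviance,
    df = df, f_value = f_value, p_value = p_value
  )
}
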