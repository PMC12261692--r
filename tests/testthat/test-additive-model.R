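# Small direct model-row builders keep these fits fast and the truth known.
make_rows <- function(n_patients, rows_per_patient, f, noise_sd = 0.3,
                      setpoint_sd = 0, seed = 1) {
  set.seed(seed)
  n <- n_patients * rows_per_patient
  pid <- rep(sprintf("P%03d", seq_len(n_patients)), each = rows_per_patient)
  offsets <- rep(rnorm(n_patients, 0, setpoint_sd), each = rows_per_patient)
  d <- tibble::tibble(
    patient_id = pid,
    date = as.Date("2015-01-01") + as.vector(replicate(n_patients,
      sort(sample.int(2000, rows_per_patient)))),
    age = rep(runif(n_patients, 20, 90), each = rows_per_patient),
    past_mean = runif(n, 6.5, 10.5),
    gender = rep(sample(c("female", "male"), n_patients, replace = TRUE),
                 each = rows_per_patient)
  )
  first <- tapply(as.numeric(d$date), d$patient_id, min)
  d$time_since_first <- as.numeric(d$date) - unname(first[d$patient_id])
  d$y <- f(d) + offsets + rnorm(n, 0, noise_sd)
  d
}

test_that("a constant response collapses to its intercept", {
  rows <- make_rows(12, 8, function(d) 0, noise_sd = 0)
  rows$y <- 8.3
  fit <- fit_additive_model(
    rows, model_spec(smooth_terms = c(past_mean = 5, time_since_first = 5))
  )
  expect_equal(fit$beta0, 8.3, tolerance = 1e-6)
  preds <- predict_with_ci(fit, rows, interval = "prediction")
  expect_equal(preds$y_hat, rep(8.3, nrow(rows)), tolerance = 1e-6)
  # zero residual variance: intervals collapse onto the point
  expect_lt(max(preds$ci_high - preds$ci_low), 1e-3)
  tc <- term_contributions(fit, rows)
  expect_lt(max(abs(tc$terms)), 1e-6)
})

test_that("a linear effect is recovered to the least-squares line", {
  truth <- function(d) 7 + 0.5 * (d$past_mean - 8.5)
  rows <- make_rows(40, 10, truth, noise_sd = 0.3, seed = 2)
  fit <- fit_additive_model(
    rows,
    model_spec(smooth_terms = c(past_mean = 10), parametric_terms = character(0),
               random_intercept = FALSE)
  )
  ols <- lm(y ~ past_mean, data = rows) # independent oracle on the same rows
  grid <- rows[order(rows$past_mean)[seq(1, nrow(rows), by = 20)], ]
  got <- predict_with_ci(fit, grid, interval = "mean")$y_hat
  want <- unname(predict(ols, grid))
  expect_lt(sqrt(mean((got - want)^2)), 0.05)

  # held-out error near the noise floor
  heldout <- make_rows(40, 10, truth, noise_sd = 0.3, seed = 3)
  err <- mspe(predict_with_ci(fit, heldout)$y_hat, heldout$y)
  expect_lt(abs(err - 0.09), 0.2 * 0.09 + 0.01)
})

test_that("predictions are additive in the term contributions and smooths are centered", {
  rows <- make_rows(30, 8, function(d) 0.3 * sin(d$time_since_first / 300),
                    noise_sd = 0.25, setpoint_sd = 0.5, seed = 4)
  fit <- fit_additive_model(rows, model_spec(
    smooth_terms = c(age = 6, past_mean = 6, time_since_first = 8)
  ))
  tc <- term_contributions(fit, rows)
  y_hat <- predict_with_ci(fit, rows, interval = "mean")$y_hat
  expect_equal(unname(tc$intercept + rowSums(tc$terms)), y_hat, tolerance = 1e-8)
  # each smooth sums to ~0 over the training covariate values
  smooth_cols <- grep("^s\\(", colnames(tc$terms), value = TRUE)
  smooth_cols <- setdiff(smooth_cols, "s(patient_id)")
  for (cl in smooth_cols) expect_lt(abs(mean(tc$terms[, cl])), 1e-8)
})

test_that("as the roughness penalty grows the smooth approaches a straight line", {
  rows <- make_rows(30, 10, function(d) 0.4 * sin((d$past_mean - 6.5) * 2),
                    noise_sd = 0.2, seed = 5)
  spec1 <- model_spec(smooth_terms = c(past_mean = 10),
                      parametric_terms = character(0), random_intercept = FALSE)
  fit_inf <- fit_additive_model(rows, spec1, sp = 1e9)
  ols <- lm(y ~ past_mean, data = rows)
  got <- predict_with_ci(fit_inf, rows, interval = "mean")$y_hat
  expect_equal(got, unname(predict(ols, rows)), tolerance = 1e-3)
})

test_that("interval levels nest and gender/patient handling is honest", {
  rows <- make_rows(25, 8, function(d) 0, noise_sd = 0.4, setpoint_sd = 0.6, seed = 6)
  fit <- fit_additive_model(rows, model_spec(
    smooth_terms = c(past_mean = 6, time_since_first = 6)
  ))
  p95 <- predict_with_ci(fit, rows, ci_level = 0.95)
  p99 <- predict_with_ci(fit, rows, ci_level = 0.99)
  expect_true(all(p99$ci_low <= p95$ci_low))
  expect_true(all(p99$ci_high >= p95$ci_high))
  expect_true(all(p95$ci_low <= p95$y_hat & p95$y_hat <= p95$ci_high))
  # prediction intervals contain the mean intervals
  pm <- predict_with_ci(fit, rows, ci_level = 0.95, interval = "mean")
  expect_true(all(p95$ci_low <= pm$ci_low & pm$ci_high <= p95$ci_high))

  # unseen patient: warning, offset zero
  new_row <- rows[1, ]
  new_row$patient_id <- "UNSEEN"
  expect_warning(pu <- predict_with_ci(fit, new_row), "unseen")
  tc <- term_contributions(fit, rows[1, ])
  re_col <- grep("patient_id", colnames(tc$terms))
  no_offset <- tc$intercept + sum(tc$terms[1, -re_col])
  expect_equal(pu$y_hat, unname(no_offset), tolerance = 1e-8)

  # unseen gender level: hard error
  bad <- rows[1, ]
  bad$gender <- "other"
  expect_error(predict_with_ci(fit, bad), "unseen gender")

  expect_error(predict_with_ci(fit, rows, ci_level = 1.2), "ci_level")
})

test_that("the mixed baseline matches the additive model when truth is linear and loses when it is not", {
  lin <- function(d) 7.5 + 0.002 * d$time_since_first
  rows <- make_rows(40, 10, lin, noise_sd = 0.3, setpoint_sd = 0.4, seed = 7)
  heldout <- make_rows(40, 10, lin, noise_sd = 0.3, setpoint_sd = 0.4, seed = 8)
  gam_fit <- fit_additive_model(rows, model_spec(
    smooth_terms = c(past_mean = 6, time_since_first = 6)
  ))
  base_fit <- fit_mixed_baseline(rows, covariates = c("past_mean", "time_since_first"))
  e_gam <- mspe(suppressWarnings(predict_with_ci(gam_fit, heldout))$y_hat, heldout$y)
  e_base <- mspe(suppressWarnings(predict_with_ci(base_fit, heldout))$y_hat, heldout$y)
  expect_lt(abs(e_gam - e_base), 0.1 * max(e_gam, e_base))

  # strong sinusoidal time effect: the additive model must win
  wig <- function(d) 8 + 0.8 * sin(2 * pi * d$time_since_first / 730)
  rows2 <- make_rows(40, 12, wig, noise_sd = 0.2, seed = 9)
  held2 <- make_rows(40, 12, wig, noise_sd = 0.2, seed = 10)
  gam2 <- fit_additive_model(rows2, model_spec(
    smooth_terms = c(time_since_first = 10), random_intercept = FALSE,
    parametric_terms = "gender"
  ))
  base2 <- fit_mixed_baseline(rows2, covariates = "time_since_first",
                              random_intercept = FALSE)
  e_gam2 <- mspe(suppressWarnings(predict_with_ci(gam2, held2))$y_hat, held2$y)
  e_base2 <- mspe(suppressWarnings(predict_with_ci(base2, held2))$y_hat, held2$y)
  expect_lt(e_gam2, e_base2)

  # constant response: intercept-only, MSPE ~ 0
  rows3 <- make_rows(10, 6, function(d) 0, noise_sd = 0)
  rows3$y <- 8.1
  base3 <- fit_mixed_baseline(rows3, covariates = "time_since_first")
  expect_lt(mspe(predict_with_ci(base3, rows3)$y_hat, rows3$y), 1e-8)
})

test_that("the mixed baseline agrees with an independent mixed-model fitter", {
  rows <- make_rows(30, 8, function(d) 7 + 0.3 * (d$past_mean - 8.5),
                    noise_sd = 0.4, setpoint_sd = 0.6, seed = 21)
  fit <- fit_mixed_baseline(rows, covariates = "past_mean")
  lmm <- lme4::lmer(y ~ gender + past_mean + (1 | patient_id),
                    data = rows, REML = TRUE)
  fe <- lme4::fixef(lmm)
  est <- setNames(fit$parametric_table$estimate, fit$parametric_table$term)
  expect_equal(unname(est["(Intercept)"]), unname(fe["(Intercept)"]), tolerance = 1e-3)
  expect_equal(unname(est["past_mean"]), unname(fe["past_mean"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(stats::sigma(lmm))^2, tolerance = 1e-2)
})

test_that("model comparison reports deviance, information criteria and nesting", {
  rows <- make_rows(30, 8, function(d) 0.2 * (d$past_mean - 8.5),
                    noise_sd = 0.3, setpoint_sd = 0.8, seed = 11)
  spec_full <- model_spec(smooth_terms = c(past_mean = 6), random_intercept = TRUE)
  spec_red <- model_spec(smooth_terms = c(past_mean = 6), random_intercept = FALSE)
  full <- fit_additive_model(rows, spec_full)
  red <- fit_additive_model(rows, spec_red)

  cmp <- compare_models(full, red)
  expect_gte(cmp$df, 0)
  expect_gte(cmp$deviance_reduced, cmp$deviance_full)
  # strong heterogeneity (SD 0.8 vs noise 0.3): random intercept significant
  expect_lt(cmp$p_value, 0.01)

  same <- compare_models(full, full)
  expect_equal(same$delta_aic, 0)
  expect_equal(same$f_value, 0)

  expect_error(compare_models(red, full), "not nested")
})

test_that("summary table mirrors the parametric-then-smooth reporting layout", {
  rows <- make_rows(20, 8, function(d) 0.1 * d$past_mean, noise_sd = 0.3, seed = 12)
  fit <- fit_additive_model(rows, model_spec(smooth_terms = c(past_mean = 6)))
  tab <- model_summary_table(fit)
  expect_identical(tab$part[1], "parametric")
  expect_true("(Intercept)" %in% tab$term)
  expect_true(any(grepl("past_mean", tab$term)))
  sm <- tab[tab$part == "smooth" & grepl("past_mean", tab$term), ]
  expect_true(sm$edf > 0 && sm$edf < 6)
  # fitting errors name the offending term
  rows_bad <- rows
  rows_bad$past_mean <- 8
  expect_error(fit_additive_model(rows_bad, model_spec(smooth_terms = c(past_mean = 6))),
               "past_mean")
})
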