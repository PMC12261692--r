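# Shared fixtures. Expensive simulation/fit objects are computed once per
# test run and cached, so several test files can share one pipeline run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Build an hb_cohort from a plain data frame by round-tripping through the
# CSV reader, so hand fixtures follow the same path as user data.
cohort_from_df <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  read_cohort(path)
}

# A hand-written five-patient measurement table used by the filter tests:
# one under-age patient, one with a single out-of-range value, one with too
# few measurements, and two fully compliant patients.
five_patient_df <- function() {
  d0 <- as.Date("2015-06-01")
  tibble::tibble(
    patient_id = rep(c("A", "B", "C", "D", "E"), times = c(3, 3, 2, 3, 4)),
    date = d0 + c(0, 30, 60,  0, 40, 80,  0, 20,  0, 15, 45,  0, 10, 20, 50),
    hb_mmol_l = c(
      8.0, 8.2, 8.1,      # A: aged 15 at first measurement
      5.9, 8.0, 8.3,      # B: one value below 6
      8.5, 8.6,           # C: only 2 measurements
      9.0, 9.2, 8.9,      # D: compliant
      7.5, 7.8, 7.6, 7.7  # E: compliant
    ),
    gender = rep(c("female", "male", "female", "male", "female"),
                 times = c(3, 3, 2, 3, 4)),
    birth_year = rep(c(2000L, 1960L, 1950L, 1945L, 1980L),
                     times = c(3, 3, 2, 3, 4))
  )
}

# Default-conditions pipeline run at moderate size, shared across files.
default_run <- function() {
  fixture("default_run", {
    run_pipeline(pipeline_config(
      synthetic = synthetic_config(n_patients = 150),
      model = model_spec(),
      seed = 2024
    ))
  })
}

# Large well-specified run for interval-calibration checks: >= 1000
# evaluated patients, no drift, fitted with the large-data engine.
calibration_run <- function() {
  fixture("calibration_run", {
    run_pipeline(pipeline_config(
      synthetic = synthetic_config(n_patients = 1200, drift_fraction = 0),
      model = model_spec(engine = "bam"),
      seed = 2024
    ))
  })
}

# Cohort with a 10% share of drift-to-abnormal trajectories for the
# SD-threshold sweep checks.
sweep_run <- function() {
  fixture("sweep_run", {
    run_pipeline(pipeline_config(
      synthetic = synthetic_config(n_patients = 500, drift_fraction = 0.10,
                                   drift_rate = -0.8),
      model = model_spec(engine = "bam"),
      seed = 2024
    ))
  })
}
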