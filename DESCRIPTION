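Package: persoref
Title: Individualized Hemoglobin Reference Ranges and Next-Value Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts each patient's next hemoglobin (Hb) value from their own
    longitudinal history with a penalized-spline additive model (smooths of
    patient age, strictly-past average Hb and time since first measurement,
    a parametric gender effect and a ridge-penalized patient random
    intercept), constructs personalized "normal" ranges as mean +/- k SD of
    the pre-holdout history, and evaluates whether the held-out most recent
    measurement falls outside the individual's bounds. Includes a synthetic
    longitudinal cohort generator with controllable setpoints, biological and
    analytical noise and drift trajectories, record-level cleaning and
    inclusion filters, a hold-out-last train/test split with no-lookahead
    feature construction, prediction intervals, confusion-matrix metrics, an
    SD-threshold robustness sweep, and one-way ANOVA intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
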