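---
title: "Personalized hemoglobin monitoring: model, ranges and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized hemoglobin monitoring: model, ranges and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Routine laboratory medicine flags a hemoglobin (Hb) result by comparing it
with a *population* reference range (roughly 7.5–10.0 mmol/L for adult
women, 8.5–11.0 for men). But Hb is a strongly individual analyte: a
patient who has sat at 9.5 mmol/L for years and suddenly measures
7.8 mmol/L is inside every population range and still clearly off *their*
baseline. `persoref` implements the individualized alternative for
longitudinal primary-care data:

1. **predict** each patient's next Hb value from their own history with a
   penalized-spline additive model,
2. **construct** a personalized "normal" range, mean ± k·SD of the
   patient's historical values, and
3. **evaluate** whether the held-out most recent measurement — and the
   model's prediction of it — falls outside those personal bounds.

## The model

For measurement $i$ the conditional mean is

$$\mu_i = \beta_0 + \beta_g\,\mathrm{gender}_i + f_1(\mathrm{age}_i)
        + f_2(\overline{\mathrm{Hb}}^{\,\text{past}}_i)
        + f_3(t_i) + b_{p(i)},$$

with $t_i$ the days since the patient's first measurement,
$\overline{\mathrm{Hb}}^{\,\text{past}}_i$ the mean of all *strictly
earlier* Hb values of that patient, $f_j$ penalized cubic regression
splines (basis dimension 10 by default, sum-to-zero centered), and
$b_{p(i)}$ a ridge-penalized per-patient random intercept. Smoothing
parameters — including the random-intercept variance — are selected by
REML (GCV is available), via `mgcv`. The response is Gaussian with
identity link: Hb level is modelled directly.

Two readings of the "average Hb" covariate are defensible; the default
`expanding_strict` recomputes it per row from strictly earlier values
(so a row never sees its own value, preserving the no-lookahead
contract), while `train_constant` gives each row the patient's constant
pre-holdout mean. The first-history row of every patient is dropped
rather than imputed, for the same reason. We model *age at measurement*
(derived from birth year with a mid-year convention) rather than birth
year itself; birth year is a monotone transform of it and the smooth is
invariant to that choice up to centering.

### Engines

`model_spec(engine = "gam")` uses exact REML; `engine = "bam"` uses
fast-REML with covariate discretization, the standard fitter for large
cohorts (thousands of patients — a random intercept contributes one
coefficient per patient, and `bam` keeps that affordable). Results agree
closely; the large simulations in the test-suite and the acceptance
script use `bam`.

## Prediction intervals

The evaluation asks whether the *next observation* falls inside the
interval, so the default interval is a prediction interval:
$\hat y \pm z_{(1+\gamma)/2}\sqrt{\widehat{se}(\hat\mu)^2 + \hat\sigma^2}$,
combining the standard error of the fitted mean with the residual
variance. A mean-only confidence interval (`interval = "mean"`) is
available. Patients absent from training get a zero random-intercept
offset (with a warning); an unseen gender level is an error, since no
defensible contrast exists for it.

## Personalized ranges and classification

A patient's range is $\bar h \pm k\,s_h$ over their pre-holdout history
$h$ (all retained measurements except the most recent), with the *sample*
SD ($n-1$ denominator — the natural choice for the short histories
involved) and default $k = 2.5$; $k = 2$ reproduces the population
mean ± 2 SD convention patient-by-patient. Boundaries are inclusive:
a value exactly on a bound is "normal", conservative toward not
flagging. A constant history yields a zero-width range rather than an
error; an analytical-imprecision floor for the half-width was considered
and deliberately left out so the mean ± k·SD formula stays exact.
Robustness to $k$ is assessed over the grid {1.5, 1.75, 2.0, 2.25, 2.5}.

The confusion matrix takes "within personal bounds" as the *positive*
class — unusual for anomaly detection, but it is the convention under
which the accompanying metric formulas (prevalence, accuracy, precision,
recall, FPR, F1) are defined; specificity and NPV are reported as the
complementary clinical view. On the published worked-example matrix
(TP 26,170 / FN 14 / FP 3,445 / TN 371) the F1 *formula* gives 93.80%,
not the 92.9% sometimes quoted next to it; the package reports the
formula value. The intraclass correlation uses the one-way
random-effects ANOVA estimator with the unbalanced-design group-size
correction $n_0$, truncated at zero.

## What the synthetic generator emulates

The clinical cohort the method targets is not publicly available, so
`synthetic_config()` encodes its published summary structure as the
package's study conditions:

| knob | default | why |
|---|---|---|
| pooled Hb mean | 8.09 mmol/L | gender-specific setpoint means 7.85 (F) / 8.44 (M) pool to 8.09 under the 59/41 female/male mix; the ~0.6 mmol/L gender gap mirrors the offset between the adult reference ranges |
| pooled Hb SD | ≈ 1.04 mmol/L | variance budget: setpoint SD 0.84² + biological within-SD 0.52² + gender-mix 0.084 + age-trend 0.008 + analytical 0.013 ≈ 1.04² |
| analytical CV | 1.43% | assay imprecision, applied multiplicatively to the noiseless value |
| age | truncated normal, mean 65.79, SD 18.34, min 17 | elderly-skewed primary-care monitoring population |
| visits per patient | round(lognormal(log 13, 0.8)) clipped to [3, 100] | right-skewed with median ≈ 13; the published summary gives the median and SD but no shape, so the log-normal is a stand-in |
| visit timing | uniform over a 7-year window, sorted | no seasonality assumed |
| age effect | 0.15 mmol/L cosine over ages 17–100, centered | a significant-but-small smooth age effect; the analytic shape gives recovery tests a known truth. Centered against the default age distribution (E[cos] = −0.365 by numerical integration) so it does not shift the pooled mean |
| drift | off by default; `drift_fraction`, `drift_rate` | monotone mmol/L-per-year drift from the patient's first visit, emulating developing abnormality |

Simulated values are clipped to positive only; range filtering is the
preprocessing stage's job. What the generator does **not** emulate:
comorbidity episodes, medication effects, seasonality, measurement
clustering around illness, informative visit timing. Tests passing on
this generator therefore demonstrate the pipeline's *statistical
correctness under its assumed structure*, not clinical performance on
real monitoring data.

## Preprocessing decisions

Same-day duplicates keep the first record in file order (deterministic
and order-stable; the source analysis says only that duplicates were
removed). Inclusion filters act on whole patients — age at first
measurement, *any* value outside the Hb range (6–16.5 mmol/L default,
per-gender bounds for the refined 6–12 F / 7–13 M subsets), and total
measurement count outside [3, 100] — and log one attrition stage each.
The minimum age defaults to 16 (the stated inclusion threshold) while
the generator's youngest simulated age is 17 (the observed minimum).
Dates are integer day offsets; no time-of-day. The hold-out-last split
reserves each patient's most recent model row for testing; a patient
whose series yields a single model row is excluded from both partitions.

## Numerical choices and degenerate inputs

Basis dimension shrinks automatically to (distinct values − 1) when a
covariate has too few levels, degrading to a linear term below 4 distinct
values, so tiny hand-written cohorts still fit. A constant response
collapses to its intercept with near-zero intervals. `mspe`, the metric
formulas and the ICC are plain closed-form arithmetic and are tested to
1e-12 against brute-force loops and `aov` mean squares. Metric
denominators of zero report `NA` rather than raising. The pipeline fans a
single global seed out to fixed per-stage child seeds (stable under
adding stages, all below 2³¹).

The nested-model deviance F test uses the *alternative* effective degrees
of freedom ($2\,\mathrm{tr}(A) - \mathrm{tr}(A^{\!\top}\!A)$, the form
appropriate for test statistics) for its df difference, and reports
`p = NA` when the extra terms carry less than half an effective
parameter: in that regime the deviance drop of a penalized term is
$\approx \mathrm{df}\cdot\sigma^2$, so F tends to 1 while its reference
distribution degenerates toward zero, and a shrunk-to-nothing random
effect would otherwise look spuriously significant.

## Design of the simulation checks

Two test designs deserve explanation, because the obvious variants fail
for *statistical* reasons that are themselves findings of the original
analysis:

- **Curve recovery** is run with the age effect amplified to 0.5 mmol/L,
  setpoint SD 0.3 and the past-mean smooth omitted, ~2,000 rows. The age
  curve is identified cross-sectionally (one age region per patient), so
  its estimation error is governed by *between-patient* dispersion; with
  the default 0.84 setpoint SD across ~120 patients no estimator could
  reach the 0.1 mmol/L target, and with the past-mean smooth included
  the age effect is partially absorbed by past-mean (the two are nearly
  collinear within patients). The check therefore isolates the question
  "does the smoother recover an identifiable curve?" from "is the design
  confounded?".
- **The random-intercept deviance test** is likewise run without the
  past-mean smooth: the past mean is itself a patient-level summary and
  soaks up setpoint heterogeneity (the full analysis observed a
  random-effect edf near zero *despite* a pre-model ICC of 0.611). With
  past-mean present the test would be insensitive by construction, which
  is a property of the model, not a defect of the test. The null scenario
  also switches the fixed age effect off: each patient occupies a single
  age region, so any lack-of-fit of the age smooth would load onto the
  per-patient offsets and contaminate the heterogeneity null. Fifty
  replicates per scenario at 40 patients each keep the check inside a few
  minutes.

Problem sizes used elsewhere: interval-calibration runs 1,200 simulated
patients (≥ 1,000 evaluated after preprocessing) with the `bam` engine;
the sweep stability check uses 500 patients with 10% drift at
−0.8 mmol/L/year; module tests run at 10–150 patients.

## Known limitations

- The generator's per-patient setpoint is constant apart from the shared
  age trend and optional linear drift; real Hb series show richer
  autocorrelation, so MSPE-type numbers from synthetic runs are
  indicative only.
- Personalized ranges need at least two historical values, and with
  3–5 values the sample SD is itself noisy; k·SD ranges inherit that
  noise. Percentile or shrinkage-based ranges are out of scope.
- The deviance F-test for a penalized random effect is approximate
  (boundary-of-parameter-space issue); we use it descriptively, as in
  the source analysis, not as a calibrated hypothesis test.
- MSPE is reported in squared units (mmol/L²) alongside its square root,
  since "MSPE in mmol/L" is dimensionally ambiguous in the source
  material.
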