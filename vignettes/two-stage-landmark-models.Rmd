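---
title: "Two-stage dynamic landmark models for 10-year risk prediction from EHR repeat measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage dynamic landmark models for 10-year risk prediction from EHR repeat measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Primary-care electronic health records hold repeated, sporadically timed
measurements of cardiovascular risk factors — smoking status, systolic blood
pressure (SBP), total cholesterol and HDL cholesterol — alongside dates of
diagnoses, prescriptions and events. Using these records for systematic risk
screening poses three difficulties: follow-up is dynamic (patients register
and leave at arbitrary times, so there is no natural baseline); single
measurements of blood pressure or cholesterol are error-prone snapshots of an
underlying level; and most patients are missing at least one marker at any
given moment.

`dynlandmark` implements a two-stage landmark approach to all three at once,
and a synthetic EHR generator with the same statistical structure so that
every stage can be exercised and validated without access to confidential
patient data.

## The model

### Landmark ages

A landmark age $s \in \{40, 45, \dots, 85\}$ is a reference point at which a
prediction is made from information recorded up to that age. At each $s$ the
eligible patients are those registered and under follow-up at $s$
(`entry_age <= s < exit_age`), free of CVD and statin prescriptions at $s$.
Each eligible patient contributes the measurement history at ages in
$[30, s]$ and a follow-up outcome capped at 10 years: time to first CVD
event, or censoring by transfer-out, death, or the administrative end of
data. Patients typically appear at several consecutive landmark ages.

### Stage 1: error-free current values

Per landmark age and sex, the four markers are modelled jointly by a
multivariate linear mixed model on the time scale $t = \text{age} - s \le 0$:

$$y_{ikj} = \beta_{0k} + \beta_{1k} t_{ikj} + \gamma\,\mathrm{BP}_{i}(t_{ikj})\,[k = \text{sbp}] + b_{ik} + \varepsilon_{ikj},$$

with correlated random intercepts $b_i \sim \mathrm{MVN}(0, G)$ ($G$ a full
$4\times 4$ covariance) and marker-specific residual variances
$\varepsilon_{ikj} \sim N(0, \sigma^2_k)$. $\mathrm{BP}_i(t)$ indicates
blood-pressure-lowering treatment at the measurement time (carry-forward),
acting on SBP only. Placing the time origin at the landmark age makes the
fixed-plus-random intercept *itself* the error-free current value at $s$ —
no extrapolation step is needed:

$$\hat\mu_{ik}(s) = \hat\beta_{0k} + \hat b_{ik} + \hat\gamma\,\mathrm{BP}_i(s)\,[k=\text{sbp}].$$

$\hat b_i$ is the empirical-Bayes BLUP
$G Z_i^\top V_i^{-1}(y_i - X_i\hat\beta)$ with
$V_i = Z_i G Z_i^\top + R_i$, computed from whatever subset of markers the
patient has ever had measured — including none, in which case the prediction
falls back to the fixed-effects prior mean. The cross-marker covariances in
$G$ let an observed SBP history inform an unobserved cholesterol level; this
is what makes the model usable for population-wide screening rather than
only for the "restricted sample" with complete marker histories.

Estimation is by direct marginal maximum likelihood: $\beta$ is profiled out
by generalized least squares, and a BFGS quasi-Newton search runs over the
Cholesky factor of $G$ (log-scale diagonal, which enforces positive
semidefiniteness) and the log residual variances, with an analytic gradient
computed in compiled code. ML rather than REML is the default so that
likelihoods are comparable across fixed-effect specifications; REML is
available as a switch in `mlmm_control()`. Convergence is declared at a
relative log-likelihood change below `1e-8` or a gradient norm below `1e-6`
(scaled), within 500 iterations; two starting points are used by default
(a moment-based start from per-patient residual means, and a diagonal-G
start) to guard against local optima. Markers never measured in a stratum
are reported as inestimable rather than silently defaulted.

Two sensitivity options mirror common concerns about EHR visit processes:
`lookback` restricts the history to a window (10 years is the conventional
choice) and `visit_rate_covariate` adds each marker's annual measurement
rate in the 5 years before $s$ as a fixed covariate, a proxy for the
sicker-patients-visit-more bias.

### Stage 2: super-landmark Cox model

The per-landmark datasets are stacked ("super-landmark") and a single Cox
proportional hazards model is fitted to the stacked rows, stratified by sex,
with time since landmark age as the time scale and Breslow tie handling.
Covariates are the landmark age and its square (centred at 60 and scaled by
10 for optimizer conditioning; coefficients are reported on that scale), the
carry-forward diabetes and BP-treatment flags at $s$, and the four stage-1
current values. Because one patient contributes several stacked rows,
standard errors use a patient-clustered sandwich estimator (practice-level
clustering is available as an option). Proportional hazards are assumed only
within the 10-year window — every row's follow-up is capped there.

The 10-year risk is
$1 - \exp\{-\hat\Lambda_{0,\text{sex}}(10)\, e^{x^\top\hat\theta}\}$ with the
Breslow baseline cumulative hazard computed per stratum from the uncentered
linear predictor.

Comparator variants re-use the same stage-2 machinery with different
covariates: `basic` (age terms and the two flags only), `last_observed` and
`cumulative_mean` (which replace the stage-1 values by the respective raw
summaries and are only defined for patients with at least one measurement of
*every* marker — the restricted sample), and `age_interactions`. For the
last, the landmark-age interaction is taken with the six risk factors
(diabetes, BP treatment, four markers), giving 14 covariates; interacting
the age term with itself would merely duplicate the quadratic column.

### Validation

All performance measures handle censoring explicitly:

* **Brier score** at 10 years: inverse-probability-of-censoring weighting
  (Graf-style) with a Kaplan–Meier estimate of the censoring distribution is
  the default; a complete-case mode (the plain mean squared difference over
  subjects whose 10-year status is known) is also provided, and the two
  coincide when no one is censored before the horizon. Both are reported
  because naive and weighted versions of this score are common in the
  applied literature and the difference is informative about censoring.
* **Harrell C-index** over pairs of *different* individuals: stacked rows of
  the same patient are never compared; the age-adjusted version restricts
  comparisons to rows at the same landmark age (and is naturally lower,
  since age itself no longer discriminates).
* **Calibration** by decile of predicted risk, with per-bin observed risk
  estimated as one minus the Kaplan–Meier survival at 10 years.
* **Cross-validation** is 10-fold *split by general practice* — whole
  practices are held out, standardization parameters and both model stages
  are refitted on the training practices only, and held-out patients receive
  out-of-sample BLUPs from the training stage-1 parameters applied to their
  own histories. A leakage audit verifies that no held-out patient entered
  any training fit.
* Confidence intervals are percentile bootstrap over patients (all of a
  patient's stacked rows resampled together, resampled copies treated as
  distinct clusters), 200 replicates by default; the clustered bootstrap is
  the conservative generic choice when rows are dependent within patient.

## The synthetic generator

`synth_config()` fixes the study conditions; `simulate_ehr()` draws a
registry and measurement table with the structure the model assumes:

* **Visit processes**: per-marker homogeneous Poisson processes within each
  patient's in-study window, with default rates `1/1.1`, `1/0.5`, `1/1.1`
  and `1/1.2` per year for smoking, SBP, total cholesterol and HDL-C — the
  mean inter-measurement gaps reported for UK primary-care records (about
  1.1, 0.5, 1.1 and 1.2 years). Visits are independent across markers by
  default, which is the simplest faithful structure.
* **Trajectories**: latent standardized marker values are linear in age with
  correlated person-level random intercepts (`default_G()`: variance 0.55
  per marker; cholesterol fractions negatively correlated, smoking
  negatively correlated with HDL-C), emitted in natural units via sex-specific
  location/scale anchored to published primary-care means (SBP ≈ 135 (21)
  mm Hg, total cholesterol ≈ 5.5 (1.1) mmol/L, HDL-C ≈ 1.4 (0.4) mmol/L).
  SBP and total cholesterol drift upward with age, smoking and HDL-C
  downward. BP-medication initiation shifts latent SBP by −0.45 SD.
* **Smoking** is generated as a continuous latent propensity by default
  (`linear-gaussian`), matching the multivariate-normal working assumption
  that stage 1 itself makes for this binary marker, so stage-1 parameter
  recovery is an exact-model check; a `bernoulli-threshold` mode emits 0/1
  values for robustness testing.
* **Outcomes**: CVD event ages are drawn from a proportional-hazards model
  on the *true* (error-free) covariate path with a sex-specific Gompertz
  baseline (rate ≈ 1.2/0.8 per 1,000 person-years at age 30 for men/women,
  log-slope 0.065 per year). Because the latent path is linear in age, the
  log hazard is piecewise linear between treatment-initiation ages and event
  ages are drawn by exact interval-by-interval inversion of the cumulative
  hazard — no discretization. Default per-SD log hazard ratios (smoking
  0.55, SBP 0.30, total cholesterol 0.22, HDL-C −0.28, diabetes 0.55, BP
  treatment 0.15) are of the magnitude conventional CVD models report and
  give roughly 7% 10-year event fractions at age 60.
* **Censoring**: transfer-out (constant hazard 0.045/year), non-CVD death
  (a small Gompertz hazard), and the administrative end of data (2016-01-18).
* **Reproducibility**: one master seed; each patient is generated from a
  deterministically derived substream, so enlarging `n_patients` never
  reshuffles earlier patients, and equal seeds give byte-identical tables.

What the generator deliberately does **not** emulate: informative
observation times beyond the visit-rate covariate (visits are not triggered
by health state), calendar trends in prescribing, practice-level
heterogeneity beyond the practice label, Read-code semantics, and competing
risks (non-CVD death censors, as in the modelling framework itself).
Passing tests on this generator therefore demonstrate internal correctness
of the estimators under the model's own assumptions — not robustness to
every way real EHRs violate them.

## Numerical and design choices

* Ages are exact fractional years (`days / 365.25`); "registration plus six
  months" is half of that.
* Boundary conventions: a measurement at exactly age $s$ belongs to the
  history; an event or statin prescription at exactly $s$ makes the patient
  ineligible at $s$, guaranteeing strictly positive follow-up.
* Plausibility limits are strict inequalities (SBP outside [60, 250] mm Hg,
  total cholesterol outside [1.75, 20] mmol/L, HDL-C outside [0.3, 3.1]
  mmol/L are set to missing); boundary values are retained.
* Standardization (sex-specific mean/SD of SBP, total cholesterol, HDL-C)
  is computed from each patient's first measurement after study entry, and
  frozen for held-out folds to prevent leakage. Smoking is never
  standardized.
* Patients with no in-window measurements stay in stage 2 with prior-mean
  stage-1 predictions; this keeps the full eligible cohort in the screening
  model. Predicted smoking values are not clipped to [0, 1] before entering
  the Cox model.
* The degenerate case $G = 0$ (available via `mlmm_control(fix_G = )`)
  reduces stage 1 to per-marker least squares and is used as an internal
  consistency check.
* In very small strata the stacked Cox fit can hit monotone likelihood
  (separation); the fit is then flagged (`$flagged`) rather than silently
  accepted. At the intended scale (thousands of patients) this does not
  occur.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script work at deliberately
reduced scale so that everything runs on a single CPU in minutes: the
end-to-end demonstration uses 2,000 synthetic patients in 10 practices with
the full landmark grid 40–85 and 10-fold cross-validation by practice;
stage-1 parameter recovery uses 20 replicates of 1,000 patients simulated
directly from the measurement model; stage-2 recovery uses one population of
5,000 patients with the generator's true current values as covariates.
These sizes were chosen as the smallest at which the Monte-Carlo checks are
sharp enough to be meaningful; all statistical conclusions (parameter
recovery within Monte-Carlo error, the ordering of cross-validated
discrimination between variants) are sample-size-robust statements, not
finely tuned thresholds.

## A worked example

```{r, eval = FALSE}
library(dynlandmark)

cfg <- pipeline_config(
  synth = synth_config(n_patients = 2000, n_practices = 10),
  landmarks = seq(40, 85, by = 5),
  variants = c("basic", "current_values"),
  cv_k = 10, n_boot = 50)
res <- run_pipeline(cfg, out_dir = "artifacts", seed = 101)

res$cv$reports$current_values   # pooled cross-validated Brier and C-index
res$cv$comparison               # delta C-index vs the basic model
```

## Known limitations

* The multivariate-normal treatment of binary smoking is inherited from the
  modelling framework; the Bernoulli emission mode exists to probe it, but
  no latent-class alternative is implemented.
* Uncertainty in the stage-1 current values is not propagated into the Cox
  model (the framework treats them as plug-in covariates).
* Joint longitudinal–survival modelling, competing risks, time-varying
  coefficients beyond the age-interaction variant, and external
  recalibration are out of scope.
* The future-average-risk-factor sensitivity variant (predicting the mean
  level over the coming decade rather than the current level) is not
  implemented; its specification depends on supplementary detail that is
  not part of this package's remit.
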