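---
title: "Modelling radiotherapy-induced hypothyroidism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiotherapy-induced hypothyroidism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroNTCP)
```

## The model

Hypothyroidism after neck irradiation is modelled as a binary 12-month
endpoint whose probability follows a logistic ("mixture") NTCP model in two
covariates,

$$\mathrm{NTCP} = \frac{1}{1 + e^{-S}}, \qquad
S = b_0 + b_{D}\,\bar D + b_{V}\,V,$$

with $\bar D$ the mean thyroid dose in Gy expressed as equivalent dose in
2 Gy fractions (EQD2) and $V$ the thyroid volume in cc. The shipped default
coefficients are $b_0 = -1.385$, $b_D = 0.093$ and $b_V = -0.188$, i.e. an
odds ratio of $e^{0.093} \approx 1.097$ per Gy of mean dose and
$e^{-0.188} \approx 0.829$ per cc of gland volume. Two sign conventions of
the logistic appear in the literature ($e^{-S}$ vs $e^{S}$ in the
denominator); only the $e^{-S}$ form is consistent with a per-Gy odds ratio
above one and risk increasing with dose, so that form is used throughout.

The model's key assumptions:

* risk depends on the dose distribution only through the mean EQD2 dose —
  a "parallel organ" view in which partial high-dose volumes matter less
  than the gland-wide average;
* volume acts protectively and linearly on the log-odds scale;
* covariates combine additively on the log-odds scale; no interactions.

Tolerance doses invert the model in closed form:
$\mathrm{TD}_{x} = (\mathrm{logit}(x) - b_0 - b_V V)/b_D$, exactly the dose
at which `ntcp()` returns $x$ (the package keeps this round trip exact to
better than $10^{-12}$). TD5/1 and TD10/1 denote 5% and 10% complication
probability at the one-year endpoint; at the median gland volume of
16.60 cc the default model gives `r round(tolerance_dose(published_ntcp_model(), 16.60, 0.05), 2)`
and `r round(tolerance_dose(published_ntcp_model(), 16.60, 0.10), 2)` Gy.

## EQD2 conversion and dose-volume metrics

IMRT delivers each voxel its own fraction size, so tolerance values quoted
for conventional 2 Gy fractionation cannot be compared with raw physical
dose. `convert_to_eqd2()` converts a physical grid voxel-by-voxel with the
linear-quadratic formula $\mathrm{EQD2} = D\,(d + \alpha/\beta)/(2 +
\alpha/\beta)$, taking the per-voxel fraction dose as $d_v = D_v / n$ for a
uniform fraction count $n$ — the simultaneous-boost situation in which every
voxel is treated in every fraction. The thyroid is late-reacting; the
default $\alpha/\beta$ is 3 Gy. The ratio is evaluated before the
multiplication so that $d = 2$ Gy is the *exact* identity in floating
point, not merely up to rounding.

`dose_metrics()` computes Dmin/Dmean/Dmax on the raw masked voxel doses
(never from the binned DVH, avoiding binning bias), the relative volumes
V10–V70 with an *inclusive* threshold (dose ≥ x Gy, the usual DVH
convention; on continuous dose the distinction has measure zero), the mask
volume in cc, and a "fractionated dose" defined as mean dose divided by the
fraction count — the natural reading of a cohort-level mean-dose-per-
fraction summary, meaningful when the physical grid is supplied.
`cumulative_dvh()` bins at 0.1 Gy by default, from 0 to the structure
maximum. Masks must already be sampled on the dose lattice; the package
does not resample contours, and no DICOM-RT adapter is included. Grids are
exchanged as raw float64 plus a small JSON geometry sidecar.

## The statistical pipeline

`run_pipeline()` reproduces a conventional clinical model-building
sequence:

1. **Univariate screening.** Each candidate factor is fitted alone against
   the outcome (`univariate_screen()`); per-unit odds ratios, Wald 95%
   intervals and Wald p-values are reported. No multiplicity correction is
   applied — deliberate, as this mirrors standard practice in this
   literature; the p-values are descriptive, not confirmatory.
2. **Collinearity clustering.** Dose metrics derived from one DVH are
   heavily interdependent. `correlation_clusters()` links factors with
   |Spearman ρ| > 0.8 and takes connected components as clusters; each
   cluster is represented by its member with the smallest univariate
   p-value (ties broken by larger |z|). Stage variables are treated as
   ordinal scores (T1–T4 → 1–4 and so on), consistent with single-
   coefficient reporting.
3. **Candidate filtering.** Only representatives that are univariately
   significant (`p_screen`, default 0.05) proceed — factors without
   marginal evidence are not offered to the multivariate model.
4. **Forward selection.** `forward_select()` starts from the intercept-only
   model and repeatedly enters the candidate with the smallest
   likelihood-ratio p-value below `p_enter` = 0.05. The LR criterion is
   used rather than Wald or conditional entry because it is the most
   reliable of the classical stepwise criteria at moderate sample sizes.
5. **Calibration.** `hosmer_lemeshow()` groups subjects by deciles of
   predicted risk (ties kept together; the grouping is reduced with a
   warning when there are fewer distinct predictions than groups) and
   refers $\chi^2 = \sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ to
   $\chi^2_{g-2}$ — the reference distribution appropriate for
   probabilities fitted on the same data.

### The logistic fitting engine

`fit_logistic()` is written in the package rather than delegated: Newton–
Raphson (equivalently IRLS) from a zero start, with step halving whenever a
full step would decrease the log-likelihood. Convergence is declared when
the log-likelihood changes by less than `tol = 1e-8` (at most
`max_iter = 100` iterations); non-convergence is flagged, never returned
silently. Wald standard errors come from the inverse observed information
at the optimum. Complete or quasi-complete separation is detected as a
coefficient exceeding 15 per standard deviation of its covariate (or a
singular information matrix) and raised as a distinct
`separation_error`, so screening loops can record the failure and continue.
Zero-variance covariates and single-class outcomes are rejected up front.
`stats::glm` serves as an independent cross-check in the test suite, never
as the implementation.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the structure the pipeline assumes, with
defaults frozen to the modelled cohort's printed distributions:

* **Volume and mean dose** are truncated normals — 16.60 ± 6.38 cc on
  [8.19, 42.00] and 41.79 ± 11.02 Gy on [10.31, 51.46]. Truncation (not
  clipping) is used because the printed extremes are data bounds. The
  source reports medians with what are treated as means ± SD; volume was
  explicitly reported approximately normal. Dmean and volume are drawn
  independently — their joint distribution is unreported. Note the hard
  upper dose bound at +0.88 SD pulls the realised mean dose down to about
  38 Gy and the mean simulated incidence to about 0.29, somewhat below the
  0.35 the point estimates suggest.
* **The collinear block.** Dmin and V20–V50 are monotone functions of
  Dmean plus noise: Dmin = 0.51·Dmean + N(0, 1.8), and
  Vx = 100·logistic((Dmean + ε − x + U(−1.5, 1.5))/6) with one shared
  ε ~ N(0, 4) per patient. The ±1.5 Gy jitter is strictly below half the
  smallest level gap (5 Gy between V40/V45/V50), which *guarantees* Vx is
  monotone non-increasing in x within every patient. The shared-noise sd
  of 4 Gy was calibrated so that the cluster's pairwise |ρ| sits safely
  above the 0.8 threshold (≈0.90 with Dmean, ≥0.81 pairwise) while Dmean
  remains the univariately strongest member — the dominance reported for
  the real cohort. V10 (high, weakly dose-related), V60, V70 (small), and
  Dmax are driven independently and only constrained to keep each
  patient's metrics ordered; the fractionated dose tracks Dmean/30.5 with
  enough noise (sd 0.28 Gy) to stay below the clustering threshold.
* **Demographics** (age uniform 11–64, gender 16/69 female, chemotherapy
  58/69, ordinal stages at the printed frequencies) are independent of
  everything, including the outcome — so age is a pure null covariate here.
* **Outcomes** are Bernoulli draws from the true NTCP model, making
  parameter recovery a well-posed check.

What the generator does **not** emulate: any real correlation between
gland volume and dose, age or gender effects on risk (reported univariate
age signals in real data have no counterpart here), longitudinal hormone
trajectories, measurement error in contouring, or realistic 3-D dose
textures (phantom fields are uniform, linear-gradient or two-level).
Passing the recovery and selection tests therefore demonstrates the
*machinery* is correct under the stated assumptions, not that the model
generalises to other cohorts.

`simulate_phantom()` builds ellipsoidal masks on regular lattices (voxel
centers inside the ellipsoid; volume agrees with $\tfrac43\pi abc$ to
within discretisation) for exercising the dose machinery against
brute-force voxel enumeration.

## Validation problem sizes

The test suite validates behaviour at sizes chosen to keep Monte-Carlo
error small relative to the tested margins: coefficient recovery and CI
coverage over 200 cohorts of n = 2000; cluster formation and forward
selection over 100 cohorts of n = 2000 (expected exact-recovery rate
≈ 95%, dominated by the 5% type-I entry chance of the null age covariate);
Hosmer–Lemeshow type-I error over 500 correctly-specified fits of n = 500;
and exact oracle agreement of metrics/DVH on 100 random phantoms.

## Numerical choices and degenerate inputs

* Logistic convergence: |Δ log-likelihood| < 1e-8, ≤ 100 iterations, zero
  start, step halving; separation threshold 15 on the per-SD scale.
* Wald intervals use the exact normal quantile (qnorm(0.975)), not 1.96.
* EQD2 identity at 2 Gy/fraction is exact by construction.
* `tolerance_dose()` warns and flags (rather than errors) when the
  closed-form dose is negative — the model is defined there, the physics is
  not; likewise curve evaluation outside the fitted dose/volume range is
  permitted, as the published volume-level curves extend across the range.
* Hosmer–Lemeshow with all-identical predictions reduces to one group and
  returns an NA p-value with a warning; fewer than 3 requested groups is an
  error.
* Empty masks, non-congruent lattices, negative doses, non-binary
  outcomes, infeasible truncation bounds and double EQD2 conversion are all
  rejected with specific messages.

## Known limitations

* The two-covariate logistic form is fixed; Lyman–Kutcher–Burman or
  relative-seriality formalisms are out of scope.
* The stepwise pipeline inherits the usual caveats of forward selection
  (post-selection inference is optimistic; p-values are nominal).
* The fractionated-dose summary assumes a uniform fraction count; plans
  with non-uniform voxel-level fractionation schedules are not supported.
* Calibration against the original patient-level cohort is not possible —
  those data are not bundled — so the shipped coefficients are taken as
  given and validated through simulation, odds-ratio and tolerance-dose
  identities rather than refitting.
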