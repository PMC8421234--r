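# thyroNTCP

Normal tissue complication probability (NTCP) modelling of hypothyroidism
after intensity-modulated radiotherapy (IMRT) of the neck.

The thyroid sits inside the prophylactic cervical irradiation field of
nasopharyngeal-carcinoma IMRT and commonly receives mean doses of 40 Gy and
more; roughly a third of patients develop (mostly subclinical)
hypothyroidism within a year. Because IMRT delivers non-conventional
fraction sizes, physical dose is first converted voxel-by-voxel to the
equivalent dose in 2 Gy fractions under the linear-quadratic model,

```
EQD2 = D * (d + α/β) / (2 + α/β),        α/β = 3 Gy for thyroid,
```

where `D` is the total dose in a voxel and `d = D / n_fractions` its dose
per fraction. Risk is then modelled logistically in the two dominant
predictors — mean thyroid EQD2 dose (Gy) and thyroid volume (cc):

```
NTCP = 1 / (1 + exp(-S)),   S = b0 + b_dmean * Dmean + b_volume * volume.
```

The package is aimed at radiotherapy outcome modellers and medical
physicists. It provides:

* **EQD2 dose grids and DVH metrics** — `dose_grid()`, `structure_mask()`,
  `convert_to_eqd2()`, `cumulative_dvh()`, `dose_metrics()`
  (Dmin/Dmean/Dmax, V10–V70, volume, fractionated dose);
* **the statistical pipeline** — a hand-written Newton/IRLS logistic engine
  (`fit_logistic()`, formula interface `ntcp_fit()` with
  `summary`/`predict`/`confint`/`residuals`/`simulate` methods),
  univariate screening (`univariate_screen()`), Spearman collinearity
  clustering at |ρ| > 0.8 (`correlation_clusters()`), forward
  likelihood-ratio selection (`forward_select()`), and Hosmer–Lemeshow
  calibration (`hosmer_lemeshow()`);
* **the NTCP model object** — `ntcp_model()` /
  `published_ntcp_model()` with `ntcp()`, `odds_ratio()`,
  `tolerance_dose()` (closed-form TDx inversion), `ntcp_curve()` and a
  `plot` method;
* **synthetic data** — `simulate_cohort()` and `simulate_phantom()`
  reproduce the cohort structure the analysis assumes (truncated-normal
  dose/volume, a built-in ρ > 0.8 collinear dose-metric block, Bernoulli
  outcomes from the model), so the full pipeline is testable without any
  patient data; `run_pipeline()` binds all stages together.

## Worked example

```r
library(thyroNTCP)

m <- published_ntcp_model()
m
#> Logistic NTCP model: NTCP = 1 / (1 + exp(-S))
#>   S = -1.385 + (0.093 x Dmean[Gy]) + (-0.188 x volume[cc])
#>   OR = 1.097 per Gy, 0.829 per cc

# complication probability for a median-sized gland (16.60 cc)
round(ntcp(m, dmean = c(20, 30, 40, 50), volume = 16.60), 3)
#> [1] 0.066 0.152 0.313 0.536

# tolerance doses: mean EQD2 dose giving 5% / 10% risk at one year
round(tolerance_dose(m, volume = 16.60, p = c(0.05, 0.10)), 2)
#> [1] 16.79 24.82
```

Risk rises with mean dose (OR 1.097 per Gy) and falls with gland volume
(OR 0.829 per cc): a 16.6 cc thyroid kept below a mean EQD2 of about 17 Gy
stays under 5% one-year risk.

The full pipeline on a synthetic cohort:

```r
coh <- simulate_cohort(cohort_sim_config(n = 1500), seed = 1)
res <- run_pipeline(coh)
res
#> NTCP pipeline: 1500 patients, 438 events
#> Representatives screened: gender, age, t_stage, n_stage, clinical_stage,
#>   chemotherapy, volume_cc, dmean_gy, dmax_gy, fx_dose_gy, v10, v60, v70
#> Selected: volume_cc, dmean_gy
#> Hosmer-Lemeshow test: chi-square = 12.116, df = 8, p = 0.146 (10 groups)
#> Tolerance doses at the cohort median volume:
#>     p volume_cc dmean_gy
#>  0.05   17.2205 19.25974
#>  0.10   17.2205 26.79599
```

The collinear block {Dmean, Dmin, V20–V50} collapsed to its representative
(Dmean), forward selection recovered exactly the generating factors
{Dmean, volume}, and the fitted coefficients (0.099/Gy, −0.167/cc) sit near
the generating values. `plot(res$curves)` draws the NTCP-versus-dose curves
at 10/15/20/25 cc.

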