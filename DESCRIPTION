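Package: thyroNTCP
Title: Normal Tissue Complication Probability Modelling of
    Radiotherapy-Induced Hypothyroidism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the risk of hypothyroidism after
    intensity-modulated radiotherapy of the neck. Converts physical dose
    grids to equivalent dose in 2 Gy fractions (EQD2) under the
    linear-quadratic model, extracts dose-volume metrics over a thyroid
    mask, screens candidate predictors with univariate logistic
    regression, collapses collinear dose metrics via Spearman rank
    correlation clustering, selects a multivariate logistic model by
    forward likelihood-ratio entry, and evaluates the resulting NTCP
    model: complication probabilities, odds ratios, tolerance doses, and
    Hosmer-Lemeshow calibration. Includes a synthetic cohort and dose
    phantom generator so the whole pipeline can be exercised and
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
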