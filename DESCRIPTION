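Package: greyzone
Title: Dual-Cutoff Evaluation of Plasma Alzheimer's Disease Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates plasma Alzheimer's disease biomarker panels (p-tau217,
    Abeta42, their ratio, and GFAP) against amyloid-PET positivity. Provides a
    seeded synthetic cohort generator calibrated to published group summaries,
    descriptive and covariate-adjusted group comparisons, ROC analysis with
    DeLong confidence intervals and APOE-augmented logistic scores, a
    bootstrap dual-cutoff framework that minimises the indeterminate
    ("grey") zone subject to predictive-value and likelihood-ratio
    constraints, and Braak-stage-stratified partial correlations between
    plasma markers and regional tau-PET uptake. All results are returned as
    tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
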