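Package: normdev
Title: Normative Modeling and Deviation Scoring for ROI-Level Diffusion MRI Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-stratified normative modeling of region-of-interest (ROI)
    diffusion MRI measures (fractional anisotropy, tissue fractional
    anisotropy and free water) as smooth functions of age, using the
    Nadaraya-Watson kernel estimator with leave-one-out cross-validated
    bandwidth selection. Individual deviations from the normative range are
    expressed as truncated z-scores, summarised per subject (load, severity,
    mean, spread, fraction in a discriminative z-range), compared between
    groups with one-tailed Welch and Wilcoxon tests plus Cohen's d and
    Cliff's delta effect sizes, and evaluated as features for case-control
    classification with ridge-penalised logistic regression under k-fold
    cross-validation with per-fold normative refitting. Includes a synthetic
    cohort generator that emulates the statistical structure of harmonized
    multi-site ROI tables, so the full pipeline is testable without access
    to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    glmnet,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
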