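Package: metsdx
Title: Rule-Based Metabolic Syndrome Classification and Diagnostic Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies participant-level cohort tables under six rule-based
    metabolic syndrome (MetS) definitions (IDF/AHA/NHLBI harmonized, NCEP-ATPIII,
    Barbosa 2006, IDF, EGIR, AACE) and evaluates each definition's diagnostic
    accuracy against the harmonized gold standard: sensitivity, specificity,
    predictive values and likelihood ratios with exact and log-method 95%
    confidence intervals, and Cohen's kappa with agreement banding. Includes
    codebook-mapped cohort ingestion with eligibility validation, sex-stratified
    descriptive tables (Pearson chi-square; t-test or Mann-Whitney routed on a
    Kolmogorov-Smirnov normality check), a seeded Gaussian-copula synthetic
    cohort generator with quantile-matched component marginals, and an
    end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    readxl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
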