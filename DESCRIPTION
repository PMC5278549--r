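Package: agemr
Title: Single-Instrument Mendelian Randomization for Longevity and Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage (instrumental-variable) Mendelian randomization for a
    single biallelic variant, built around the design of two-arm longevity and
    ageing cohort studies. Provides genotype quality control (allele
    frequencies, Hardy-Weinberg equilibrium testing, additive and dummy
    coding), cumulative-deficit frailty-index and modified Fried
    frailty-phenotype scoring, the two-stage estimator with an adjustment-model
    ladder and joint-resampling bootstrap validation, the Wald-ratio
    cross-check, reconstruction of regression quantities from per-genotype
    summary statistics, and a synthetic-cohort generator that emulates a
    case-control longevity arm and a cross-sectional ageing arm so every stage
    of the pipeline is testable without individual-level study data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
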