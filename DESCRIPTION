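Package: liquidtrial
Title: Liquid-Biopsy-Guided Trial Analysis: Tumor-Fraction-Adjusted Plasma
    Copy Number, Biomarker Stratification and Exact Phase-II Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for circulating tumor DNA (ctDNA)-guided
    biomarker studies in single-arm oncology trials. Implements sample-level
    ctDNA metrics (maximum somatic variant allele fraction, tumor fraction,
    tumor-fraction-adjusted plasma copy number, clonal versus subclonal
    classification), baseline predictive-biomarker stratification (concurrent
    RTK/RAS/PI3K pathway alteration detection, rank-based ROC analysis with
    Youden threshold selection, favorable-factor classification), on-treatment
    ctDNA-fraction monitoring with RECIST-style response confirmation,
    paired baseline/progression comparison for acquired resistance, the exact
    single-stage binomial phase-II design with Clopper-Pearson intervals, and
    survival statistics (Kaplan-Meier, log-rank, Cox hazard ratios). A
    synthetic-cohort generator emulates longitudinal plasma and tissue
    genotyping tables so every pipeline stage is testable without patient data.
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
    survival,
    tibble,
    tidyr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
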