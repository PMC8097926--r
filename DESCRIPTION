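Package: contexture
Title: Quantitative Immune-Contexture Analysis of Multiplex
    Immunohistochemistry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of multiplex
    immunofluorescence immunohistochemistry (mIHC) cell-segmentation data
    from tumor biopsies: reading and validating per-cell tables with
    tumor/stroma compartment labels, marker-combination phenotyping,
    compartment-specific cell densities and percentages with per-patient
    aggregation, cell-to-cell proximity statistics (nearest-neighbor mean
    distance and fraction of cells within a radius), derived prognostic
    scores (median dichotomization, Immunoscore, lymphoid/myeloid
    concordance groups, RECIST disease-control classification), and a
    survival layer (Kaplan-Meier, log-rank, Cox hazard ratios,
    Mann-Whitney and Spearman comparisons). Includes a synthetic
    tissue-cohort generator with known ground truth so the full pipeline
    is testable end to end without patient data.
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
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
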