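Package: circaprot
Title: Circadian Actigraphy Metrics and Label-Free Proteomics Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used in
    aged-mouse circadian and proteomic phenotyping studies: chi-square
    periodogram rhythmometry with nonparametric rest-activity statistics
    (interdaily stability, intradaily variability, relative amplitude),
    activity-onset period regression and re-entrainment scoring after a phase
    advance; label-free quantitative (LFQ) proteomics differential expression
    with left-censored missing-value imputation, Welch's t contrasts with a
    z-score cutoff and a reversal-signature filter; weighted protein
    correlation network analysis (signed topological overlap, module
    eigengenes, module-trait correlation, hypergeometric gene-set enrichment);
    and group statistics (two-way ANOVA with Tukey post hoc, repeated-measures
    stress effects, Spearman correlation matrices). A synthetic-data module
    generates wheel-running records, LFQ matrices and trait tables with known
    ground truth so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
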