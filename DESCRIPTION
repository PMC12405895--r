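Package: clonegx
Title: Genetic Parameters, Multitrait Selection and Phenotypic Stability
    for Multi-Environment Clonal Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-environment clonal (vegetatively propagated)
    field trials laid out as randomized complete blocks with multi-tree plots.
    Fits the clone / site-by-clone / plot / residual linear mixed model by
    restricted maximum likelihood (REML) with sparse mixed-model equations,
    predicts genotypic values by BLUP, and derives the classical genetic
    parameters of tree breeding: genotypic coefficient of variation, clonal
    repeatability (broad-sense heritability), type-B genotypic correlation,
    and genotypic and phenotypic between-trait correlations from bivariate
    fits, with Delta-method standard errors. Ranks clones by a two-trait
    selection index with data-driven weight optimization and selection
    differentials, and quantifies per-clone phenotypic stability with the
    harmonic mean of relative performance of genotypic values (HMRPGV) and a
    BLUP-based Wricke ecovalence with Shukla-variance significance testing.
    Includes a simulator that emulates the full trial design (mortality,
    one-ramet-per-plot wood-trait subsampling, configurable variance strata)
    so every stage of the pipeline is testable without field data.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
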