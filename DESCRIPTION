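Package: poolgarden
Title: Pool-Seq Diversity Estimation and Common-Garden Design for Experimental
    Plant Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational chain of common-garden invasion
    experiments that assemble artificial populations along a genetic-diversity
    gradient. Estimates allele frequencies, unbiased expected heterozygosity
    and pairwise FST from pooled-sequencing read counts; applies tiered SNP
    filters; designs stratified population mixtures spanning the diversity
    gradient; models longitudinal census and harvest data with quasi-Poisson
    and zero-inflated Gamma regressions; and ships a synthetic-data layer
    (island-model pool-seq reads and common-garden outcomes with known effects)
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    MASS,
    car,
    emmeans,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, ExperimentalDesign, Regression
RoxygenNote: 7.3.3
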