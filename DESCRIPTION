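Package: tipnpred
Title: Polygenic Prediction Models for Persistent Taxane-Induced
    Peripheral Neuropathy Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Staged construction and held-out validation of polygenic
    logistic prediction models for persistent taxane-induced peripheral
    neuropathy symptoms from whole-exome variant data. Provides
    variant-level quality control (genotyping rate, mean coverage,
    Hardy-Weinberg exact test, biallelic/PASS filters), per-variant
    logistic association scans under additive, dominant and recessive
    codings with permutation-based false discovery rate threshold
    selection, variance-component score tests for rare-variant gene
    regions, hypergeometric gene-set over-representation filtering,
    combination with literature variant panels, Wald-statistic variable
    importance pruning, and ROC/AUC evaluation with bootstrap confidence
    intervals and accuracy-targeted cutoff selection. A synthetic cohort
    generator with planted variant and covariate effects supports
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
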