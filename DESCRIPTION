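Package: pbeqtl
Title: Cell-Type-Resolved Pseudobulk cis-eQTL Mapping with Multivariate
    Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for cell-type-resolved pseudobulk cis-eQTL
    analysis of single-cell cohorts: cell/gene/cell-type QC filters and
    mean-aggregation of normalized log-expression, variant-level QC
    (minor allele frequency, exact Hardy-Weinberg test, windowed LD
    pruning), genomic relationship matrices, linear mixed-model
    association with kinship and cell-count random effects, disease
    interaction eQTL mapping with permutation calibration, multivariate
    empirical-Bayes shrinkage of effects across cell types with local
    false sign rates, sharing and global/multi/unique classification of
    eQTLs, Bayesian colocalization with GWAS summary statistics under
    the five-hypothesis single-causal-variant model, and Fisher
    enrichment testing with distance-matched null sets. A synthetic
    cohort generator with a recorded ground-truth table makes every
    stage testable without access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    MASS,
    knitr
Config/testthat/edition: 3
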