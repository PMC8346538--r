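Package: PRSstrat
Title: Polygenic-Risk-Score Stratified Case-Control GWAS
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a clumping-and-thresholding polygenic risk score (PRS)
    workflow for dissecting heterogeneous case-control phenotypes: a cohort is
    split in half, a PRS is trained on one half with the SNP-inclusion P-value
    threshold selected by AUC on the other half, cases and controls are
    dichotomized at the MCC-optimal PRS cutoff, and a covariate-adjusted
    logistic GWAS restricted to the low-PRS stratum is compared against the
    overall GWAS by an odds-ratio heterogeneity z-test, with replication by
    cohort switch. Ships a synthetic two-subtype cohort generator (a majority
    subtype driven by common large-effect variants and a minority subtype
    driven by rare variants) so the whole pipeline is testable without access
    to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociationStudies, SNP, StatisticalMethod, Genetics
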