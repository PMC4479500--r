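Package: methylseg
Title: HMM Segmentation and Differential Methylation Analysis of Array
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential methylation inference for Illumina 450K-style
    array profiles of tumor subtypes. Segments genomically ordered
    M-value profiles with a diagonal-Gaussian hidden Markov model,
    selects differentially methylated probes (DMPs) through three
    concurrent routes (per-probe and per-segment Mann-Whitney testing
    with Benjamini-Hochberg correction and stratified-bootstrap
    stability validation, plus logistic-LASSO selection of
    discriminating HMM states under the one-standard-error rule), calls
    differentially methylated regions (DMRs) from adjacent DMPs,
    performs Fisher-exact functional and chromosomal enrichment, and
    summarizes imprinting-control-region and X-chromosome methylation.
    Includes a seeded synthetic cohort generator with planted
    differential blocks for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    GenomicRanges,
    glmnet,
    IRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
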