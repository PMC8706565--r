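Package: tsRNAtriage
Title: Serum tRNA-Derived Small RNA Biomarker Pipeline for Radiation Biodosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classification, quantification and triage modelling of circulating
    tRNA-derived small RNAs (tRFs and tiRNAs) as radiation-exposure biomarkers.
    Provides hierarchical one-mismatch read mapping against mature tRNA,
    precursor tRNA and miRNA references, coordinate-based tsRNA subtype calls,
    CPM expression matrices with abundance filtering and symmetric fold-change
    screening across dose groups, 2^-ddCt relative quantification of qPCR
    validation panels with exogenous spike-in normalisation, and multi-marker
    linear exposure-risk scoring with ROC/AUC triage evaluation. A seeded
    synthetic-data module emulates serum small-RNA libraries and Ct tables so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Sequencing, Classification, qPCR
LinkingTo: Rcpp
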