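Package: CDIndex
Title: Clustering Deviation Index for Single-Cell RNA-Seq Clustering Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood-based evaluation of candidate clustering label sets for
    UMI count data from single-cell RNA sequencing. Scores each label set by the
    penalized negative maximized log-likelihood (AIC/BIC flavours) of a
    gene-specific, cell-type-specific negative binomial model, with
    likelihood-ratio testing of batch effects and degrees-of-freedom accounting.
    Includes dispersion-based (WDS) feature-gene selection, binned chi-squared
    goodness-of-fit tests for negative binomial families, seeded negative
    binomial population simulators, and rank-agreement utilities (ARI,
    Fowlkes-Mallows, NMI, Spearman) for benchmarking internal indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    jsonlite
biocViews: SingleCell, Clustering, Transcriptomics, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
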