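Package: xplat
Title: Cross-Platform Transferability of Expression-Based Predictive Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses whether gene-expression predictive models and their
    signature genes transfer between microarray and RNA-seq platforms.
    Maps array probe sets to RNA-seq genes by public gene IDs or genome
    location, partitions features into mapping-complexity groups A-D,
    trains ensembles of k-NN, nearest-shrunken-centroid and SVM classifiers
    (and Cox survival models) on one platform under a stratified
    resampling/forward-selection protocol, carries signatures or whole
    fitted models to the other platform, and quantifies transferability
    with the T-index, Cohen's kappa and concordance-index comparisons.
    Includes a synthetic paired-platform data generator with controllable
    per-group cross-platform concordance for end-to-end exercise of the
    pipeline.
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
    rtracklayer,
    survival,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
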