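Package: PrognoSig
Title: Genomic Aberration Signatures and Immune Scores for Breast Cancer Prognosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines weighted gene-expression signatures for recurrent somatic
    mutations and copy-number events in estrogen-receptor-positive breast
    cancer, scores individual tumors with a rank-based foreground/background
    enrichment statistic calibrated against a permutation null, derives
    reference-profile immune infiltration scores, and integrates signature,
    immune and clinical features in random-forest classifiers and Cox
    proportional-hazards models of recurrence risk. Includes aberration
    calling from MAF and segmented copy-number input, a synthetic-cohort
    generator with planted ground truth for end-to-end validation, backward
    feature elimination, DeLong tests for correlated ROC curves, and
    cross-validated concordance.
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
    rtracklayer,
    survival,
    randomForest,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
biocViews: GeneExpression, Survival, Classification, CopyNumberVariation,
    SomaticMutation, ImmunoOncology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
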