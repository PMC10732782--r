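Package: PhosphoStack
Title: Phosphosite Prediction with Stacked Gradient Boosting and Homology Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein phosphorylation sites (serine, threonine,
    tyrosine) from per-residue protein language model embeddings using a
    stacking classifier built from two gradient-boosted tree base learners
    (equal and balanced class weights) combined by a logistic meta-learner
    trained on out-of-fold probabilities. Includes a pairwise-alignment
    homology-transfer step that promotes predicted false positives to
    inferred positives when their 31-mer peptide window aligns onto an
    experimentally supported phosphosite, precision/recall/F-beta evaluation
    machinery with ROC and precision-recall curves, deterministic synthetic
    fixtures for end-to-end testing, and export of predicted sites to
    genome-browser GFF3 tracks via codon-level coordinate mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
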