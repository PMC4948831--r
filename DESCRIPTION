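Package: qirnapred
Title: Prediction of qiRNA-Like Small RNAs from Positional Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies short RNA sequences (~15-25 nt) as qiRNA-like or
    background using log2-odds scores derived from position probability
    matrices (PPMs) over the terminal positions of each sequence, optional
    k-mer frequency features, F-score feature ranking, and a random-forest
    classifier. Includes construction of length-matched negative training
    sets from non-coding RNA pools (non-overlapping fragmentation with
    optional nucleotide shuffling), stratified n-fold and leave-one-out
    cross-validation with fold-local featurization, confusion-matrix
    metrics (sensitivity, specificity, accuracy, Matthews correlation
    coefficient), ROC/AUC computation, a synthetic-data generator for
    end-to-end testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    optparse,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
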