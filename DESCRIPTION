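Package: siRNAfeat
Title: Feature Engineering for siRNA Off-Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds machine-learning feature representations for predicting
    off-target effects of chemically modified small interfering RNAs (siRNAs).
    Provides nine dataset variants spanning simple positional sequence
    encodings, per-position and compressed circular (extended-connectivity)
    fingerprints of nucleotide monomers and modified dimers, a 24-bit byte
    encoding of Ensembl gene identifiers, and structure-derived per-residue
    displacement features obtained by Kabsch superposition of modeled
    siRNA-Argonaute complexes onto a reference structure. Includes label
    binarization from log2 fold-change tables, a replicate-reproducibility
    metric (sum of relative standard deviations of residue displacements),
    synthetic fixture generators for end-to-end testing, and an
    imbalance-aware evaluation harness with stratified splits, confusion
    metrics, precision-recall curves and impurity-based feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    class,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    arrow,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
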