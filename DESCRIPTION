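Package: allerfuse
Title: Allergenic Protein Prediction from Fused Sequence Composition Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies protein sequences as allergenic or non-allergenic from
    composition-based features. Encodes sequences with amino acid composition
    (AAC), dipeptide composition (DPC) and the composition of k-spaced amino
    acid pairs (CKSAAP), fuses the encodings into a single 1620-dimensional
    feature vector, ranks features by Pearson correlation with the class label,
    shrinks the selected subset with principal component analysis and trains a
    random-forest classifier. Includes a stratified cross-validation and
    hold-out evaluation harness (accuracy, sensitivity, specificity, MCC, ROC
    and precision-recall curves), a seeded two-class synthetic protein sequence
    generator for end-to-end testing without external data, and optional
    logistic-regression, support-vector-machine and k-nearest-neighbour
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    e1071,
    class,
    stats,
    utils
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
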