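Package: irespred
Title: Prediction of Internal Ribosome Entry Sites in 5'UTR Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trainable classifier for internal ribosome entry sites (IRES)
    in 5' untranslated regions. Candidate sequences are represented by 35
    features: eight general sequence/structure properties (length, upstream
    AUG count, the hairpin/external/internal/multibranch/total loop counts
    of the predicted minimum-free-energy secondary structure, and its
    folding energy) together with predicted interaction probabilities
    against a panel of 27 small-subunit ribosomal proteins, obtained from a
    conjoint-triad/k-mer sequence-encoding classifier or from precomputed
    tables. A support vector machine over the scaled feature vectors is
    tuned by particle-swarm or grid search under stratified k-fold
    cross-validation, and evaluated by a repeated stratified
    split/train/test protocol reporting accuracy, sensitivity, specificity,
    precision and the Matthews correlation coefficient. Includes a seeded
    synthetic-data generator so the whole pipeline runs without external
    downloads, an adapter for Vienna-compatible folding engines with a
    built-in maximum-base-pairing fallback, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    randomForest,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
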