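Package: lbmodel
Title: Local-Balanced Models for Classifying Instrumental Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Local-balanced classification for two-class feature tables from
    mass spectrometry and other instruments. For every test sample a bespoke
    training set is assembled from the nearest labelled samples of each class
    (Euclidean distance in full feature space), with the per-class subset
    sizes exposed as independent tunable parameters, and a fresh base
    classifier (support vector machine by default) is trained on that subset
    to classify that one sample. Includes delimited/ARFF loaders with the
    preprocessing steps common in the field (total-signal normalization,
    column scaling, zero-feature removal, target-class binarization),
    non-redundant pairwise feature-ratio expansion, imbalance-aware
    evaluation metrics (rank AUC, G-mean, minority F-measure), group-size
    optimization by leave-one-out AUC, synthetic data generators that mimic
    intensity drift, noisy peak traces and class imbalance, and a
    config-driven command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    pROC,
    foreign,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
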