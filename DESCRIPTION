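Package: labelsieve
Title: Ensemble Cross-Validation Detection of Mislabeled Image Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects mislabeled samples in labeled image datasets with an
    ensemble of classifiers trained under a cross-validation scheme: every
    sample is scored exactly once as unseen data, disagreeing predictions
    above a softmax confidence threshold are tallied as votes, and k-of-m
    majority or consensus rules flag suspect labels whose true class is then
    recovered by ensemble plurality.  Includes a nanopore translocation
    signal simulator that renders current-trace segments into images, a
    separable multi-class image generator, controlled label-flip injection,
    precision/recall/F1 evaluation with threshold-by-rule sweeps, a small
    trainable convolutional network family used as desk-scale base learners,
    and KNN/k-means/PCA baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    class,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
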