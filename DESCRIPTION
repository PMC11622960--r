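Package: leafhash
Title: Deep Supervised Hashing for Plant Leaf Disease Image Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deep-hashing toolkit for content-based retrieval of plant leaf
    disease images. Trains a compact convolutional network with a hash layer
    and a softmax classifier head under a combined pairwise-likelihood /
    quantization / cross-entropy objective, binarizes the relaxed codes with a
    sign activation, and answers queries by Hamming-distance ranking optionally
    stratified by the predicted class. Includes the class-balancing
    augmentation pipeline (flip, gamma, noise, PCA colour, rotation, scale),
    retrieval evaluation (precision/recall/F-score, AP/MAP at k, ROC/AUC), a
    procedural leaf-image generator with a controllable inter-class similarity
    dial for desk-scale experiments, and an ablation harness over loss
    variants, hash-layer use and code lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
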