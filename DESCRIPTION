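Package: SparseMIL
Title: Sparse-Attention Multiple-Instance Learning for Megapixel Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of large microscopy images from
    image-level labels only, via deep multiple-instance learning (MIL). An
    image is a bag of equal-sized non-overlapping patches (instances); a small
    shared convolutional encoder embeds each patch and a pooling module
    aggregates either embeddings (EMIL) or per-instance predictions (IMIL)
    using max-pooling, softmax attention, or sparsemax attention. Sparsemax
    projects attention logits onto the probability simplex and yields exact
    zeros, so non-informative patches are discarded entirely; training adds
    L0 and entropy penalties on the attention distribution. Includes a
    field-of-view cropper and patch tiler for microscope images, patient-wise
    stratified splitting, a seeded synthetic bag generator emulating
    smartphone-on-microscope histopathology images, stochastic
    gradient-descent training with reverse class weighting and flip
    augmentation, ROC/AUC evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
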