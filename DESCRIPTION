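Package: cacpnet
Title: Channel Attention and Channel Pruning for Compact Leaf-Disease
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains, profiles and compresses ResNet-18-style
    convolutional classifiers for plant leaf disease images. Implements an
    efficient channel-attention module that combines global average and
    global max pooling with a local cross-channel 1D convolution, and a
    structured channel-pruning procedure driven by norm-based channel
    importance and per-block local compression ratios with residual-shortcut
    index sharing. Includes closed-form FLOPs/parameter/size profiling, a
    seeded synthetic leaf-disease image generator, stratified splitting and
    rotation/flip amplification, an SGD training and evaluation harness with
    confusion-matrix, ROC/AUC and Grad-CAM reporting, and an end-to-end
    insert-attention, train, prune, retrain pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    EBImage
Config/testthat/edition: 3
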