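Package: weakseg
Title: Weak-Label Bootstrapping for Vesicle Segmentation in High-Throughput
    Screening Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for training semantic-segmentation networks on weak
    (noisy) labels produced by conventional image processing, applied to
    two-channel fluorescence microscopy of autophagy vesicles reported by a
    dual-fluorophore pH biosensor. Provides a seeded synthetic image simulator
    with pixel-perfect ground truth, a difference-of-Gaussians/top-hat/watershed
    weak labeler with a controlled label-corruption model, a from-scratch U-net
    trainer with generalized dice loss and SGD-with-momentum, and a three-pronged
    evaluation suite (per-class pixel metrics with global/mean/weighted
    aggregation, bounding-box surrogate detection analysis, and two-sample
    Kolmogorov-Smirnov comparison of rating scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
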