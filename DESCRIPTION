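Package: tanhrelunet
Title: TanhReLU Convolutional Neural Networks for EEG Segment Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained deep-learning toolkit for classifying 4-second
    multichannel EEG segments (major depressive disorder versus healthy
    control) with a small convolutional neural network built around the
    TanhReLU activation, a piecewise fusion of the hyperbolic tangent and a
    half-slope linear tail controlled by a segmentation parameter.  Provides
    the activation family with analytic derivatives and discontinuity
    diagnostics, from-scratch differentiable layers (depthwise and standard
    2-D convolution, fully connected, batch normalization, sigmoid head,
    mean-squared-error loss) each with a finite-difference-verified backward
    pass, EEG windowing into channel-stacked 32x32 tensors, EDF ingestion, a
    seeded synthetic EEG generator with class-dependent alpha-band power over
    1/f background noise, and the full training recipe: stochastic gradient
    descent with weight decay, early stopping, confusion-matrix metrics,
    learning curves and leave-one-out validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
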