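Package: engramnet
Title: Dropout in Engram-Like Convolutional Networks as a Model of Deep
    Brain Stimulation Effects on Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates the paradoxical disruption and enhancement of memory
    by neurostimulation as dropout of engram nodes in a small convolutional
    classifier of handwritten glyphs.  Provides a from-scratch, finite-
    difference-verified network engine (two valid 3x3 convolution layers,
    2x2 max pooling, global max pooling, a 100-unit fully connected layer),
    a phase-aware inverted-dropout operator restricted to the fully
    connected layer, a synthetic EMNIST-like glyph generator plus an IDX
    reader/writer, and seeded multi-replicate experiment harnesses for
    dropout placement, dropout-rate sweeps, and transfer learning with
    output-head replacement, with bootstrap summaries, learning-curve
    plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
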