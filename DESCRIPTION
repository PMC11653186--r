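Package: evocnn
Title: Genetic-Algorithm Architecture Search for Compact Convolutional
    Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves convolutional network architectures for two-class
    grayscale image classification with a genetic algorithm over
    variable-length chromosomes of per-layer filter counts and kernel
    sizes (or dense-head widths for a frozen feature extractor).
    Provides uniform and length-altering crossover, bounded additive
    mutation, elitist survivor selection and plateau-based stopping;
    confusion-matrix and accuracy fitness functions with cross-entropy
    losses and an architecture cost; a directory-tree image loader with
    rotation/zoom/shift/flip augmentation; a synthetic two-class
    radiograph-like image generator with tunable separability; and a
    small CPU training backend so the full search loop runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
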