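Package: glandclass
Title: Hand-Crafted Feature Classification of Prostate Gland Candidates in
    H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-stage prostate cancer assessment at the level of
    individual gland candidates segmented from H&E-stained histology patches.
    Implements tissue-component mapping by per-channel k-means clustering with
    morphological post-processing, a 241-entry hand-crafted descriptor
    combining gland/lumen morphology, directional Hurst-exponent fractal
    analysis, gray-level co-occurrence matrices, rotation-invariant uniform
    local binary patterns with local-variance histograms, and contextual
    relations between tissue components; statistical feature selection
    (Kolmogorov-Smirnov normality gate, ANOVA or Kruskal-Wallis class tests,
    pairwise decorrelation); and patient-wise nested cross-validation of a
    two-stage quadratic-kernel SVM cascade and a single-hidden-layer
    perceptron. A synthetic H&E gland-phantom generator with ground-truth
    component maps, and a fractional-Gaussian-noise image synthesiser, make
    the whole pipeline testable without any external image database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
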