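Package: histocascade
Title: Cascaded Deep-Wavelet Feature Fusion for Histopathology Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cascaded classification of microscopy images at a binary
    (normal versus tumor) and a four-subtype level, aimed at pediatric
    medulloblastoma histopathology. Images are embedded with convolutional
    backbone feature extractors read out at the global-average-pooling
    layer, each embedding is converted to its single-level discrete Meyer
    wavelet detail coefficients, the three coefficient sets are fused and
    reduced by discrete cosine transform truncation or principal component
    analysis with a sequential forward search over the retained dimension,
    and the reduced features are classified with linear and cubic support
    vector machines, 1-nearest-neighbour, linear discriminant analysis, or
    a random-subspace discriminant ensemble. Evaluation uses repeated
    stratified k-fold cross-validation with accuracy, sensitivity,
    specificity, and precision. A deterministic synthetic texture fixture
    generator makes the full cascade testable without any image download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    EBImage,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    yaml,
    optparse
Config/testthat/edition: 3
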