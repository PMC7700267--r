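Package: phytodetect
Title: Detection of Phytoplankton Specimens in Conventional Bright-Field
    Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fully automatic detection, merging and classification of
    phytoplankton specimens in multi-specimen bright-field microscope
    images. Implements adaptive Gaussian thresholding of the RGB channels
    for foreground-background separation, contour-based candidate
    detection with physical-unit area and border filters, Delaunay-graph
    merging of sparse colonies, bag-of-visual-words descriptors over RGB
    colour or complex Gabor filter-bank texture responses, and a set of
    classical classifiers selected by cross-validated grid search with
    precision-at-recall fitness. Ships a seeded synthetic scene generator
    with exact ground truth so the whole pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    igraph,
    jsonlite,
    mclust,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
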