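Package: cappheno
Title: Machine-Vision Phenotyping of Mushroom Caps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based phenotyping of single mushroom caps photographed on a
    uniform colored background. Provides KD-tree-seeded k-means color
    segmentation, local-binary-pattern texture scoring with half-Gaussian
    suppression of surface-crack responses, a Sobel gradient edge chain with
    contour extraction and small-area filtering, eleven morphometric and color
    traits with pixel-to-millimeter calibration, correspondence-based edge
    evaluation (ODS, OIS, average precision), and cap-weight prediction with an
    RBF support vector regression whose hyperparameters are tuned by a Grey
    Wolf Optimizer. A seeded synthetic-cap generator supplies images with exact
    edge, mask and phenotype ground truth so every stage is testable without a
    camera rig.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
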