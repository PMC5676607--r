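Package: mlpard
Title: Weed Patch Mapping from Multispectral Imagery with an
    ARD-Regularised Multilayer Perceptron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel classification of invasive weed patches (milk thistle,
    Silybum marianum, against drying graminaceous vegetation) from
    three-band multispectral imagery (green, red, near-infrared) fused
    with a 7x7 local-variance texture layer. The classifier is a
    one-hidden-layer multilayer perceptron with a logistic output,
    trained by minimising a cross-entropy objective with group-wise
    weight decay whose hyperparameters are re-estimated under MacKay's
    evidence framework (automatic relevance determination, one weight
    group per input feature plus three bias/output groups). Includes a
    seeded synthetic-scene generator emulating the patchy two-class
    structure such imagery exhibits, polygon-based pixel sampling with
    class balancing and a 70/30 calibration/validation split,
    confusion-matrix evaluation with row percentages, Hinton-diagram and
    per-feature relevance exports, and whole-scene map deployment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
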