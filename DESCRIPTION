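Package: retphasor
Title: Spectral Phasor Analysis of Multispectral Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying retinal health from multispectral fundus
    image cubes using the spectral phasor transform. Provides reflectance
    calibration from white-reference and dark-current images, band-wise
    Z-score normalization with percentile trimming, per-pixel phasor
    transforms at selectable harmonics, whole-retina and region-of-interest
    feature summarization, repeated hold-out evaluation of four classical
    classifiers, and two-group MANOVA with Wilks' Lambda. Includes a
    synthetic multispectral fundus data generator so that the full pipeline
    is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    png,
    jsonlite,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
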