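Package: thermoface
Title: Facial ROI Localization and Emotion Recognition from Paired
    Visual and Infrared Thermal Images
Version: 0.1.0
Authors@R:
    person("ThermoFace", "Developers", email = "thermoface@example.org",
           role = c("aut", "cre"))
Description: Tools for locating facial regions of interest (ROIs) on
    infrared thermal images of the face using a paired visual camera.
    Implements homography-based transfer of detections between camera
    planes, head-width-proportional ROI sizing, relocation of
    automatically placed ROIs against a single expert-annotated
    reference frame via normalized-coordinate softmax error
    probabilities, a 154-dimensional thermal appearance feature set
    (14 statistics per ROI over 11 ROIs), and emotion classification by
    PCA dimensionality reduction followed by Gaussian discriminant
    classifiers with stratified cross-validation.  A synthetic
    face-phantom generator with full ground truth makes every stage of
    the pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
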