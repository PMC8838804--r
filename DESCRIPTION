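Package: articulometry
Title: Keypoint-Based Measurement of Speech Articulator Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for evaluating markerless keypoint estimates of speech
    articulators (tongue, lips, hyoid, jaw) against hand labels. Reads
    DeepLabCut-style keypoint CSV files, interpolates anatomical control
    points into dense cubic-spline contours, and computes a modified mean
    sum of distances (MSD) curve-similarity statistic whose endpoint rule
    makes it insensitive to relative contour length, together with a
    separate spline length difference, confidence-gated keypoint RMSE,
    lip width/aperture/rounding measures, and bite-plane-aligned Pearson
    correlation between electromagnetic articulography sensor trajectories
    and estimated keypoints. Includes a synthetic-data generator producing
    tongue contours, lip frames and paired sensor/keypoint sessions so the
    whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
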