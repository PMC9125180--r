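Package: pawtrack
Title: Kinematics, Spatial Occupancy and Unsupervised Behavior
    Classification from Animal Pose-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyzes per-frame body-part coordinates produced by markerless
    pose estimation (e.g. the DeepLabCut CSV dialect). Conditions low
    likelihood points, calibrates pixels to centimeters, and computes
    traveled distance, speed, acceleration and head orientation; builds
    occupancy heatmaps and detects interaction events with user-defined
    rectangular or circular areas; classifies behaviors per frame without
    supervision from pairwise body-part distances via Ward agglomerative
    clustering and a heuristically tuned t-SNE embedding scored by
    neighborhood-, class- and distance-preservation metrics; and couples
    detected behaviors to synchronized neural signals through epoch
    extraction and spatial activity maps. Includes synthetic-data
    generators with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
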