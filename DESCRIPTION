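Package: plugsim
Title: Simulation of Airway Mucus Plugs in CT Volumes and Lesion-Level
    Detection Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates anatomically constrained synthetic mucus plugs inside
    segmented airway trees of chest CT volumes, for annotation-free training
    of detection and segmentation models. Provides procedural airway/vessel
    phantom generation with ground-truth masks and centerlines, signed
    Euclidean distance fields, constrained region growing of plugs with
    sampled length, occlusion ratio and host-airway caliber, depth-matched
    vessel-to-airway intensity transfer, isotropic resampling and balanced
    patch extraction for dataset export, and lesion-level evaluation
    (Dice, overlap-based true/false positive matching, size-stratified
    sensitivity with score confidence intervals, false positives per scan,
    paired comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
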