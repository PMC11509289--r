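Package: hipnav
Title: Precision Assessment of CT-Based Surgical Navigation for Acetabular Cup Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing the precision of
    CT-based hip-navigation systems in total hip arthroplasty. Implements rigid
    3D geometry (Kabsch superposition, transform composition, rotation metrics),
    anterior and functional pelvic plane coordinate frames built from anatomical
    landmarks, acetabular cup orientation angles (operative, radiographic and
    anatomic conventions) and a signed cup-depth metric, sparse point-to-surface
    rigid registration with multi-start initialisation (the intra-operative
    patient alignment), dense surface registration of post-operative to
    pre-operative scenes with cup-pose transfer, a fully seeded synthetic pelvis
    scene generator with known ground truth, and study-level navigation-error
    statistics (mean, SD, range, absolute-value summaries, exceedance
    percentages, box/scatter plot data exports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
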