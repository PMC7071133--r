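Package: holosteps
Title: Obstacle-Crossing Kinematics from Markerless Depth Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for obstacle-crossing experiments recorded with
    depth sensors. Simulates cohorts of hurdle-crossing trials with planted
    ground truth, converts depth frames and foot point clouds into per-foot
    lower-edge time series, computes per-trial crossing kinematics (maximum
    step height, crossing height, foot clearance, collisions, forward
    velocity), detects participants whose holographic-obstacle avoidance
    deviates from real-obstacle avoidance via classical multidimensional
    scaling of per-participant outcome vectors, quantifies feedback-induced
    changes across trial blocks with t-based confidence intervals, and
    provides epsilon-corrected repeated-measures ANOVA with Bonferroni
    post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
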