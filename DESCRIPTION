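Package: wheelvault
Title: Markerless Motion Analysis of Wheel-Gymnastics Vault Mounts
Version: 0.1.0
Authors@R:
    person("wheelvault", "maintainers", email = "wheelvault@example.org",
           role = c("aut", "cre"))
Description: Rule-based key-frame detection, kinematic feature construction
    and execution-score (E-score) modelling for Unit 2 of the wheel-gymnastics
    vault (take-off through the final position before the thrust). Detects the
    four key frames from dense optical-flow summaries and segmentation-mask
    geometry, builds the 21 pose features used to score the mounting phase,
    estimates judge deductions with a random-forest regressor (mean-squared-
    error splits, impurity-based feature importances, root-to-leaf rule
    extraction), and reproduces the threshold-group hypothesis tests
    (Dunnett many-to-one, Mann-Whitney U). A synthetic vault simulator with
    known ground-truth events and deductions makes every stage testable
    without video data or neural networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mvtnorm,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
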