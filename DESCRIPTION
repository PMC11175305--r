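Package: emghybrid
Title: Simulation and Analysis of EMG-Driven Hybrid Rehabilitation with Motion Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse an electromyography (EMG)-driven
    hybrid rehabilitation workflow for 2-DOF wrist pointing. Includes causal
    Butterworth preprocessing of multichannel surface EMG into sum-to-one
    muscle-coordination feature vectors with an activation gate, a recurrent
    log-linearized Gaussian-mixture network (R-LLGMN) classifier for motion
    intent estimation, minimum-jerk instruction trajectories, a sigmoid
    current-joint-angle model for open-loop functional electrical stimulation
    (FES) with least-squares calibration, a quantitative pointing-evaluation
    metric suite (endpoint error, lateral deviation, endpoint spread, orbit
    correlation, jerk cost, normalized mean velocity, reaching time), seeded
    synthetic-data generators for EMG and pointing trials, and an in-silico
    motor-learning experiment pipeline with Bonferroni and Mann-Whitney group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
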