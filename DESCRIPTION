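Package: reachtone
Title: Closed-Loop Movement Sonification and Reach Kinematics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free implementation of a closed-loop behavioral
    feedback system for head-fixed mouse forelimb reaching. Pose streams in
    the multi-header pose-estimation CSV dialect (or from a built-in
    behavior simulator) are converted frame-by-frame into vertical forepaw
    displacement, driven through a trial state machine with target-zone
    detection, reward bookkeeping and refractory gating, and sonified by a
    linear displacement-to-frequency map (2-20 kHz) with phase-continuous
    offline synthesis. An offline analysis pipeline segments reaches,
    aligns and resamples trajectories, embeds them with PCA and t-SNE,
    clusters them with Gaussian mixtures selected by BIC, and computes
    normalized left/right reach ratios with per-day Welch tests, two-way
    repeated-measures ANOVA and Cohen's d. A cohort simulator with planted
    learning effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
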