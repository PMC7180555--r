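Package: comeal
Title: Cost-Sensitive Collaborative Multi-Expert Active Learning for Wearable Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adapting human-activity-recognition models to new
    subjects, sensors, or activity classes at minimal annotation cost.
    Implements a collaborative multi-expert active-learning loop: a random
    forest learner with entropy and leaf-purity query strategies, a pool of
    heterogeneous simulated annotators (perfect, imperfect, and on-demand
    experts) with per-label uncertainty vectors and confidence-proportional
    costs, greedy cost-minimising expert assignment with an exact
    small-instance oracle, transfer-learning initialization that matches
    unlabeled target clusters to the most similar labeled source domains,
    and a synthetic multi-subject inertial sensor world generator so every
    algorithm is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
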