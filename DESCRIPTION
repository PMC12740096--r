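Package: mazetraits
Title: Longitudinal Cognitive Phenotyping from Radial-Maze and Object Tests in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-session performance metrics for the nine-arm radial
    maze (decision-making time, working-memory errors, unique-sequence
    decomposition and the weighted unique-sequence score, learning rate,
    exploration ratio, cumulative arm time, velocity), novel-object preference
    ratios and open-field occupancy measures from region-entry event logs.
    Provides a stochastic null model of arm choice with an exact analytic
    companion distribution, per-age Z-score standardisation with Stouffer
    combination, slope-regularised linear trait-stability regression,
    per-mouse lifespan trends with decliner detection, exhaustive
    metric-subset search ranked by mean coefficient of determination, and
    subsample-resampling robustness curves. A synthetic-cohort generator with
    controllable trait stability, age effects and planted decliners makes the
    whole pipeline testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
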