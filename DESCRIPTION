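Package: combgrow
Title: Morphometrics and Stochastic Growth-Retraction Modelling of
    Comb-Like Sensory Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and simulating the development of
    comb-like proprioceptive sensory dendrites (Drosophila larval class I
    vpda neurons). Provides SWC tree input/output and resampling, automatic
    main-branch detection and alignment, branch-length ordering and
    orientation-angle morphometrics (49 branching statistics), wire-optimality
    scaling analysis against greedy minimum-spanning-tree synthetic
    morphologies, a geometric model of branch bending curvature on a
    cylindrical body wall, in-silico terminal-branch retraction schemes,
    single-branch time-lapse dynamics classification, an iterative stochastic
    growth model with timed stochastic retraction, segment-contraction and
    ratiometric calcium trace analysis, and seeded synthetic-data generators
    with ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
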