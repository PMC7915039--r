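Package: graspglove
Title: Secure-Grasp Detection and Agency-Based Feedback Training Analysis
    for an Instrumented Sensor Glove
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for instrumented-glove grasp
    training studies. Provides a seeded synthetic-data generator emulating
    multi-channel force/flex sensor trials and motion-capture object
    trajectories; secure/insecure frame labeling from steady-hold
    statistics; a per-subject feedforward neural-network grasp detector
    trained by scaled conjugate gradients with early stopping, alongside an
    analytical pinch force-equilibrium baseline; feedback scheduling with
    an intentional-binding delay ramp; kinematic performance metrics
    (completion time, pathlength, placement error); and a within-subject
    normalization, outcome-measure and statistics layer (repeated-measures
    and one-way ANOVA, Tukey post hoc with optional Bonferroni scaling,
    one- and two-sample t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
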