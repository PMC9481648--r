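Package: copair
Title: Kinematics and Coupled Optimal Control of Pair Table Carriage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse and model the locomotion of two humans carrying a
    table together. Provides motion-capture preprocessing (zero-phase Butterworth
    filtering, lift-based trial segmentation, pelvis and table planar-pose
    extraction, time normalization), trajectory similarity metrics (pointwise
    linear and angular curve distances, averaging, forward/return symmetry,
    configuration-optimality classification), a coupled two-agent holonomic
    optimal-control trajectory model with exponential barrier couplings solved
    by differential dynamic programming, bi-level inverse optimal control to
    recover cost weights from average trajectories, a synthetic study-design
    generator, and the statistical analysis battery (non-parametric rank and
    exact tests) used to characterise pair carriage strategies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
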