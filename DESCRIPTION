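Package: jointfriction
Title: Whole-Joint Coefficient of Friction from Pendulum Oscillation Decay
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale measurement chain for whole-joint friction testing of
    small-animal knees with a passive pendulum: Coulomb stick-slip simulation
    of the free oscillation about a frictional fulcrum, rendering and rigid
    registration of reflective-marker trajectories, amplitude-envelope peak
    detection with a Stanton linear-decay fit to recover the coefficient of
    friction, a calibrated generator for longitudinal paired-limb loading
    studies across lubricin (Prg4) genotypes including ordinal cartilage
    histology scores, and the downstream statistics (mixed model on log
    coefficient of friction, two-way ANOVA on histology, rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
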