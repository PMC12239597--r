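Package: gearbelt
Title: Quantification of Rotary Motor Direction, Gliding Motility, and
    Conveyor-Belt Adhesin Transport in Bacteroidetes
Version: 0.1.0
Authors@R:
    person("gearbelt", "developers", email = "gearbelt@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the three single-cell assays used to
    characterise rotational-direction control of the bacterial type 9
    secretion system (T9SS): tethered-cell rotation (signed rotational
    frequency and CCW/CW direction with a full-revolution inclusion
    filter), phase-contrast gliding motility (trajectory linking, gliding
    speed, farthest displacement, turn/reversal events), and TIRF
    tracking of the mobile cell-surface adhesin SprB along the
    conveyor belt (spot detection, speed, trajectory-shape
    classification). A stochastic tri-component gearset simulator
    (motor ensemble -> belt -> cell kinematics) and a synthetic
    microscopy renderer provide seeded ground-truth fixtures so every
    stage is testable without external data. Supporting statistics
    include Gaussian kernel density estimation, the exact two-tailed
    Mann-Whitney U test, in-circle region probability, a spin-angle
    collective variable, and work integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
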