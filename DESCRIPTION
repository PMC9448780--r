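Package: mechanopfl
Title: Bistable Mechanical Positive-Feedback-Loop Model of Fibroblast Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a minimal three-variable ordinary differential equation
    model of the integrin beta-1 / Piezo1 mechanical positive feedback loop that
    drives cardiac fibroblast activation on stiff extracellular matrix. Provides
    equilibrium enumeration with stability classification, saddle-node and
    hysteresis analysis, mechanical-dose ("stiff-then-soft") transfer protocols
    with reversibility classification, in-silico inhibitor treatment scenarios
    and phase diagrams, the closed-form quantification formulas used alongside
    such experiments (nuclear/cytoplasmic intensity ratio, rheometry-derived
    elastic modulus, swelling ratio, relative expression by the 2^-ddCt method),
    a seeded synthetic-data layer, and least-squares recovery of model
    parameters from time-course data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
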