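Package: glycohif
Title: Kinetic Modelling of HIF-1 Driven Glycolysis and Lactate Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles and integrates a 26-state kinetic model of the
    glycolysis pathway in which hypoxia, acting through the transcription
    factor HIF-1, drives the levels of twelve glycolytic enzymes and
    transporters by mass-action induction. Provides Michaelis-Menten and
    reversible rate laws, a configurable oxygen to HIF-1 mapping, stiff ODE
    integration of hypoxia scenarios, classification of metabolite
    concentration changes, oxygen sweeps of the intracellular lactate level,
    a one-at-a-time sensitivity scan of the HIF-1 induction constants, a
    synthetic parameter-set generator with steady-state construction and
    target calibration, SBML Level 3 export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
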