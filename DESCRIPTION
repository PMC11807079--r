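Package: cnsivive
Title: Bottom-Up Prediction of Rat Brain Extracellular Fluid Pharmacokinetics from Transwell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scales in vitro transwell permeability and corrected efflux-ratio
    measurements to in vivo blood-brain-barrier clearances (passive diffusion and
    P-glycoprotein efflux, the latter via a proteomics-informed relative expression
    factor), drives them through a compartmental ODE model of the rat CNS
    (microvasculature, brain extracellular fluid, brain cell membranes) forced by
    empirical plasma pharmacokinetic models, and evaluates predictions against
    unbound microdialysis concentrations with a symmetrized prediction-error and
    fold-error framework, including expression-bandwidth scenario analysis and
    permeability/efflux sensitivity sweeps. Ships the literature parameter tables
    as fixtures and a seeded synthetic-microdialysis generator so the full
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
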