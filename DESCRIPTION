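Package: ckdflow
Title: System Dynamics Simulation of Chronic Kidney Disease Progression
    Under Healthcare Disparities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A deterministic stock-and-flow simulation toolkit for studying
    chronic kidney disease (CKD) progression under healthcare disparities.
    Provides a generic fixed-step system dynamics engine with mass-balance
    checking, a signed causal-loop-diagram module with feedback-cycle
    enumeration and reinforcing/balancing polarity classification, a CKD
    stage-ladder model in which cumulative bias (patient, primary-care
    provider, nephrologist, healthcare system) drives unmonitored treatment
    and faster stage progression, and scenario, parameter-sweep and
    endpoint-calibration machinery for base-versus-altered-rate experiments.
    Models round-trip through a YAML configuration, trajectories through CSV,
    diagrams through DOT, and stock-flow models export to XMILE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
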