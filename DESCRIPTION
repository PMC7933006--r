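Package: trpflux
Title: Expression-Constrained Kinetic Modelling of Hepatic Tryptophan Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic model of tryptophan (Trp) metabolism in hepatocytes, with
    enzyme and transporter capacities scaled per replicate by gene-expression
    data, steady-state concentrations and fluxes computed by stiff ODE
    relaxation with a damped Newton polish, and normoxia-versus-hypoxia
    differences summarised by unpaired two-tailed t-tests with significance
    codes. Includes a seeded synthetic expression-table generator emulating
    hypoxic regulation of the kynurenine and tryptamine branches, SBML Level 3
    export, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    xml2,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
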