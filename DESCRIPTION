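Package: rhoswitch
Title: Bistability Analysis of the Rac1-RhoA-PAK Signaling Switch
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modeling and bistability analysis of the double-negative
    feedback network formed by the small GTPases Rac1 and RhoA coupled through
    the kinase PAK, GEF-H1 and Rac GAPs. Provides the 14-species mass-action /
    Michaelis-Menten ordinary differential equation model with conserved
    protein moieties, stiff integration via a compiled right-hand side,
    multi-start steady-state detection with stability classification,
    one-parameter hysteresis sweeps with up- and down-switch thresholds,
    two-parameter bifurcation region maps, random sampling of protein
    abundance space with monostable/bistable classification, in-silico PAK
    inhibitor dose/washout protocols with first-order intracellular clearance,
    synthetic single-cell population generation with lognormal abundance
    variability, Gaussian-mixture bimodality testing of readout distributions,
    and least-squares parameter recovery from synthetic dose-response data.
    Models are exportable to SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    mclust,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
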