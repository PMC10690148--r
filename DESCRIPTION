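Package: edisim
Title: Simulating Extended-Prime Vaccine Dosing Regimens and Germinal Center Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing vaccine dosing regimens (bolus, multi-dose
    exponentially escalating, two-dose extended prime, and extended-release
    variants) in silico. Implements a deterministic kinetic model of innate
    immune activation, dendritic cell recruitment, antigen loading and T
    follicular helper cell priming in the draining lymph node, together with
    a stochastic agent-based germinal center model in which B cells compete
    for native (intact) or non-native (degraded) antigen held on follicular
    dendritic cells as antibody-mediated immune complexes. Includes a
    two-parameter fit of the priming model to day-14 Tfh counts, a lognormal
    synthetic-cohort generator for testing the fitting pipeline, and an
    experiment driver that writes tabular outputs for regimen sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
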