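Package: lobuleflow
Title: Finite-Volume Simulation of Blood Flow and Drug Metabolism in a Liver Lobule Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based lattice model of a liver lobule for hepatic
    drug clearance studies. Builds a quarter-lobule grid of sinusoid channels
    interlaced with hepatocyte tissue cells, solves steady and transient
    single-phase Darcy pressure flow with a two-point flux approximation,
    integrates multicomponent advection-diffusion transport of a drug
    (paclitaxel) and its metabolite with Michaelis-Menten elimination
    localized in tissue cells, and computes the process-timescale report
    (pressure relaxation, diffusion, reaction, breakthrough) that
    rationalizes the simulated regimes. Exports effluent time series,
    gridded field snapshots (legacy-ASCII VTK and CSV), and machine-readable
    run summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
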