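Package: impactcurves
Title: Abundance-Impact Curve Models for Invasive Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation models of how the impacts of an invasive
    suspension-feeding bivalve (Dreissena) depend jointly on its abundance
    and on the invaded ecosystem. Implements a cumulative shell-accumulation
    model (first-order dissolution of spent shell under variable production
    forcing), an instantaneous macrophyte-habitat model chaining population
    filtration rate through chlorophyll, Secchi depth, light extinction and
    lake hypsography to colonizable bottom area, and a landscape sampling
    study contrasting within-system, cross-system-snapshot and cross-system
    long-term abundance-impact curves, including per-capita effect measures
    and nonlinear-averaging (Jensen) gaps. Seeded lognormal AR(1) generators
    supply invader trajectories and landscapes of lakes, and a small
    configuration layer ties the stages into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
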