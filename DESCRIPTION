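Package: kinlattice
Title: Stochastic Lattice Simulation of Dual-Kinesin Axonal Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates anterograde transport of two kinesin species
    (a fast, highly processive kinesin-3 and a slower, weakly processive
    kinesin-1) along bundles of parallel, discontinuous axonal microtubules.
    The engine is a totally asymmetric simple exclusion process with
    Langmuir-kinetics detachment and reattachment through finite,
    position-anchored reservoirs, multi-site hops, lateral lane changes,
    and staggered (blocked) lattice regions that emulate axonal injury.
    Includes eight single-segment injury scenarios, linked multi-segment
    axons with junction reservoirs, pulsed-input clearance experiments,
    event metrics (detachment rates, dynamicity maps, temporal outflow),
    and a mean-field master-equation integrator used as an independent
    validation oracle in reduced limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
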