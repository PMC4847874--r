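Package: cytomech
Title: Mechanochemical Simulation of Contractile Actomyosin Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator for active cytoskeletal networks coupling
    compartmentalized stochastic reaction-diffusion chemistry (Gillespie direct
    and next-reaction methods) to coarse-grained semi-flexible polymer mechanics.
    Actin filaments are represented as chains of stretchable cylinders with
    bending, stretching, branching, boundary and an analytic segment-segment
    excluded-volume potential; alpha-actinin cross-linkers and non-muscle myosin
    IIA mini-filament ensembles bind, unbind and walk with force-dependent rates
    (Brownian ratchet, slip bond, coarse-grained motor ensemble kinetics).
    Includes the accompanying analysis suite: radius of gyration, nematic
    ordering tensor, anomalous-diffusion exponents of filament centers, and
    bundle polarity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
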