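Package: skinmarkov
Title: Spatial Markov-Chain Simulation of Skin Cancer Progression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lattice-based two-state spatial Markov-chain simulator of skin
    cancer progression. Nodes on a rectangular grid switch irreversibly from
    a susceptible to a cancerous state with exponential hazards driven by
    nearest-neighbour contamination (distance-scaled rates) and by a
    phenomenological lifetime UV-exposure burden (surface-only or
    depth-attenuated). Includes the analytic non-spatial two-state chain as
    a validation benchmark, a fixed-step (tau-leaping) sampler with an exact
    event-driven (Gillespie) oracle, Monte Carlo uncertainty quantification
    of the time for cancer to occupy a target fraction of the domain
    (mean, Monte Carlo error, empirical CDF, input-output correlations),
    and bisection calibration of the base rate against Gompertz-type tumor
    mass growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
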