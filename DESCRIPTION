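Package: pendisc
Title: S-System Metabolic Network Models from Time-Series Metabolite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs S-system (power-law) models of metabolic reaction
    networks from time-series metabolite concentrations. The equations are
    non-dimensionalized around a steady state so that a single dimensionless
    rate constant remains per metabolite pool; flux-balance constraints
    derived from the network structure (linear chains, branch points,
    confluences) reduce these further to one free constant per linear
    pathway plus one per branch point. Kinetic orders are fixed at +/-0.5
    (configurable), and the remaining free constants are estimated by
    Levenberg-Marquardt fitting of integrated trajectories to the data.
    Hidden (unmeasured) metabolites are handled by co-estimating their
    dimensionless rate constant and recovering their steady-state
    concentration from the branch-point flux balance. Includes trajectory
    simulation, steady-state solving in log-concentration space, noise
    injection, leave-one-out cross-validation, perturbation-response
    prediction, and synthetic benchmark fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
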