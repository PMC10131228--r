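Package: milekin
Title: Markovian Milestoning Kinetics from Cell-Confined Stochastic Sampling
Version: 0.1.0
Authors@R: person("Milekin", "Developers", email = "milekin@example.org",
    role = c("aut", "cre"))
Description: Estimates ligand unbinding kinetics and thermodynamics with
    Markovian milestoning on Voronoi tessellations (MMVT) of a scalar
    collective variable. Per-cell trajectories confined by reflective
    boundaries are reduced to milestone collision statistics, combined into
    a milestone-level rate matrix, and solved for mean first passage times
    (residence times), stationary probabilities and free-energy profiles.
    Includes a synthetic-dynamics generator (confined overdamped Brownian
    dynamics on configurable potentials, exact Gillespie jump processes,
    brute-force first-passage oracles, and a steered-pulling seeding
    routine) so the full pipeline runs self-contained, plus replica
    aggregation, Welch tests and residence-time ranking of multiple
    systems through a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
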