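Package: seqforage
Title: Sequential Target Foraging: Look-Ahead Choice Models, Optimal
    Planning and Simulation
Version: 0.1.0
Authors@R:
    person("Jonas", "Keller", email = "jonas.keller@posteo.net",
           role = c("aut", "cre"))
Description: Tools for analysing rapid sequential target-harvesting
    (foraging) behaviour. Implements a probabilistic cost/softmax model of
    target-by-target choice in which the cost of a candidate target
    combines its negative reward rate, a power-law distance penalty and a
    size penalty, optionally looking several harvests ahead with
    temporally discounted weights. Provides maximum-likelihood fitting
    with multiple simplex restarts, BIC-based submodel and look-ahead
    depth comparison, a rate-maximising optimal planner, simulated agents
    for synthetic sessions, and diagnostic summaries (selection
    probabilities and ranks, tier selection proportions, movement-distance
    distributions, and shortest-path ranking for the constrained task).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
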