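Package: coopnet
Title: Social Planners for Networked Cooperation Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for turn-based cooperation games on
    dynamic networks. Players on a graph repeatedly choose to cooperate (paying a
    per-neighbour cost and conferring a per-neighbour benefit) or defect, while a
    "social planner" recommends edge additions and deletions that players accept
    or reject. The package provides the game engine; logistic bot models of human
    play with maximum-likelihood fitting; rule-based planners (static, random,
    cooperative clustering, encouragement, density-matching, maximum-density); a
    graph-network planner trained by advantage actor-critic against simulated
    groups; and the network analysis suite (cooperation trajectories,
    recommendation breakdowns, choice assortativity, degree bias, core-periphery
    structure with permutation tests, Gini/Lorenz inequality).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    igraph,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
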