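Package: valleycross
Title: Fitness Valley and Plateau Crossing in Subdivided Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic simulation and analytic theory for the crossing of
    fitness valleys and plateaus by asexual populations subdivided into demes
    coupled by migration. Provides an exact Gillespie simulator of the
    metapopulation dynamics (logistic birth-death with mutation and pairwise
    individual exchange, plus a fixed-size Moran validation scheme and a
    hub-and-spoke island topology), Moran fixation probabilities,
    sequential-fixation and stochastic-tunneling crossing-time predictions,
    champion-deme order statistics, the tri-diagonal birth-death Markov chain
    over mutant-fixed demes with closed-form absorption statistics, and the
    optimal migration-rate window within which a metapopulation crosses as
    fast as its fastest deme.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
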