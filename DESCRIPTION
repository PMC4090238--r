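Package: campnet
Title: Network Modelling of Camper Travel and Forest Pest Dispersal Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a bi-directional origin-destination network model of
    recreational camper travel and uses it to estimate the relative risk of
    human-mediated forest pest dispersal (for example bark- and wood-boring
    insects moved in firewood) between gridded map locations. Trip records
    are filtered to a seasonal window of peak insect emergence, aggregated
    onto an equal-area grid, augmented with return segments, and scaled into
    a sub-stochastic transition matrix that drives absorbing random-walk
    simulations of camper itineraries. The per-pair visit frequencies give a
    relative dispersal risk score, which can be summarised as forward
    profiles (likely destinations), reverse profiles (likely origins), and
    jurisdiction-level out-of-state origin-risk maps with hotspot
    classification. A synthetic trip generator with a quantile-calibrated
    lognormal distance kernel makes the full pipeline testable without
    access to reservation data, and an exact hitting-probability solver
    provides an analytic cross-check of the simulated risk estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    Matrix,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
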