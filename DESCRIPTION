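Package: recakinetics
Title: Nucleation-and-Growth Kinetics of RecA Filaments on dsDNA from
    Force-Clamp Single-Molecule Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse the polymerization of RecA on double-stranded DNA measured
    with force-clamp optical tweezers. Converts force-extension traces into
    contour-length and protein-coverage kinetics through a mixed-stiffness
    worm-like-chain model, decomposes stepwise coverage curves into the
    kinetics of individual protein domains and their asymmetric fronts,
    simulates the few-nuclei nucleation-and-growth process with a Monte-Carlo
    model, and infers nucleation rate, growth rate and front-asymmetry ratio
    by chi-square comparison of simulated and measured ensemble coverage.
    Includes closed-form fast- and slow-nucleation limits, activation-energy
    differences, and a synthetic-data generator emulating lambda-DNA scale
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
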