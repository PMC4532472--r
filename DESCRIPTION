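Package: abridger
Title: Timescale-Separation Abridgment of Stochastic Chain Reaction Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Model reduction ("abridgment") for stochastic linear chain
    reaction systems such as multisite phosphorylation cascades. Builds the
    chemical master equation generator of a reversible chain with a slow exit
    reaction, computes the relaxation time of the fast subsystem from the
    spectral gap, derives the reduced single-reaction rate from the chain's
    equilibrium occupancy, and checks the timescale-separation condition under
    which the reduction is accurate. Includes an exact Gillespie direct-method
    simulator (compiled), first-exit-time analysis via matrix exponentials,
    builders for a multisite-phosphorylation bistable switch (Cdh1/Clb2) and
    its reduced form, and distribution-distance diagnostics comparing the
    full and abridged models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
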