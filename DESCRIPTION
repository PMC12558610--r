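Package: socnorm
Title: Evolutionary Stability of Social Norms under Indirect Reciprocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical tools for indirect reciprocity with public, binary
    reputations. Represents third-order social norms (an action rule plus a
    possibly stochastic assessment rule), folds in assessment, implementation
    and perception errors, computes the stationary fraction of good players
    and the long-term value of a good reputation, and evaluates exact
    evolutionary-stability (ESS), cooperative-ESS and equalizer conditions,
    including a costly-punishment action. Ships independent brute-force
    oracles (finite-horizon value recursion, mutant-invasion payoffs, a
    finite-population Monte Carlo simulator) so every analytic verdict can be
    cross-checked, plus enumeration of all deterministic cooperative ESS
    (the leading-eight and secondary-sixteen families).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
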