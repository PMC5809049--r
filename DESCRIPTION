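Package: codonDS
Title: Differential-Selection and dN/dS Codon Models for Convergent and
    Positive Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian codon models for contrasting convergent directional
    selection with classical positive selection on protein-coding genes.
    Implements mutation-selection (Halpern-Bruno) codon models with site- and
    condition-specific amino-acid fitness profiles (DS2/DS3), omega-based
    codon models with site- and condition-specific dN/dS (OM1/OM3),
    branch-condition partitioning of a phylogeny from tip phenotypes, an MCMC
    sampler alternating stochastic substitution mapping with
    Metropolis-Hastings updates, posterior decision rules for differential
    and positive selection, sequence-logo matrix export, and an exact
    (Gillespie) forward simulator of codon alignments used for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phytools,
    Biostrings,
    jsonlite,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
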