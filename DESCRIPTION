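Package: wfgp
Title: Gaussian-Process Likelihood Inference for Evolve-and-Resequence
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-based inference for genomic time
    series from evolve-and-resequence (E&R) experiments.  Models
    allele-frequency trajectories sampled over tens of generations as a
    Gaussian process whose mean and covariance are obtained from moment
    approximations to the discrete multi-locus Wright-Fisher process with
    diploid selection and recombination.  Provides a forward Wright-Fisher
    simulator with founder-panel generation and pooled sequencing,
    closed-form neutral two-locus moments, a delta-method moment recursion
    for one-, two- and three-locus models with a linked selected site,
    likelihood-ratio tests for selection with an empirical null,
    maximum-likelihood estimation of selection coefficients, dominance,
    recombination hotspot intensity and effective population size, and a
    two-pass genome-scan pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
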