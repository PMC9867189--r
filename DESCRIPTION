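Package: idpcg
Title: Coarse-Grained Simulation and Sequence-Patterning Analysis of
    Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-letter (neutral, cohesive, positively and negatively
    charged) bead-spring heteropolymer model of intrinsically disordered
    proteins, evolved by overdamped Brownian dynamics (Ermak-McCammon) with
    optional Rotne-Prager-Yamakawa hydrodynamic interactions. Provides
    sequence-patterning metrics (sequence charge decoration, kappa), static
    observables (end-to-end distance, radius of gyration, gyration-tensor
    asphericity, Kirkwood hydrodynamic radius, conditional end-to-end
    distributions and the two-points-in-a-sphere reference model), dynamic
    observables (end-to-end vector and distance autocorrelation functions,
    rotation and reconfiguration times), and effective-homopolymer
    calibration of heterogeneous sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
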