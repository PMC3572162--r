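Package: nucleocg
Title: Coarse-Grained Nucleosome Core Particle Modelling and Langevin Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a bead-resolution coarse-grained model of the nucleosome
    core particle (residue-level histone octamer with an elastic network, ten
    flexible charged histone tails, and two-base-pair five-bead helical DNA
    wrapped on a 1.75-turn superhelix), simulates it by Langevin dynamics with
    explicit mobile counterions in a periodic dielectric continuum, and
    analyses the results: radial and body-frame spatial distribution
    functions, pair-distance spectra with radius of gyration and maximum
    dimension, optimal-superposition RMSD, DNA geometry statistics, stacking
    geometry and bulk ion concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
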