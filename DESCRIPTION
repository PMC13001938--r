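Package: microstress
Title: Generative Machine-Learning Pipeline for Oil-Contamination Biomonitoring
    from Microbial Community Compositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts oil contamination of water microcosms from 16S-derived
    bacterial count tables with a compact generative pipeline: autoencoder
    compression of categorical metadata (oil type, sampling location) to single
    decodable scalars, random-forest feature ranking of taxa against encoded oil
    type, noise-injected data augmentation through a feedforward network (ADNN),
    variational-autoencoder generation of in-distribution stress-test samples,
    a batch-normalized prediction network, and a leakage-guarded bottle-level
    repeated hold-out evaluation. Includes a seeded synthetic-community
    generator (zero-inflated negative-binomial counts with planted
    oil-responsive taxa) so every stage is testable end to end without real
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
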