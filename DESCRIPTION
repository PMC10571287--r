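Package: daric
Title: Quantitative Differential Chromatin Compartmentalization from Hi-C
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies each genomic bin's preferential interaction with the
    active (A) versus repressive (B) chromatin compartment from distance-
    normalized Hi-C contact matrices (the Preferential Interaction Score,
    PIS), removes systematic scale and offset differences between samples by
    robust regression in MA coordinates, segments residual PIS into
    differential compartmentalization domains with a Gaussian-emission hidden
    Markov model, and assigns empirical significance from biological
    replicates. Includes a multi-sample variability mode (conserved/variable
    compartment states), feature enrichment in domains, and a fully specified
    synthetic-data generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
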