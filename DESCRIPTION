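Package: coposeq
Title: Monte Carlo Simulation of Parallel-Successive Copolymer Sequences
    and Selective Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates step-growth copolymerization of telechelic oligomer
    pools assembled by the parallel-successive (P-S) strategy, in which two
    oligomer populations of controlled length and cleavable-unit content are
    coupled in an alternating AA/BB fashion.  Oligomer lengths follow the
    Flory most-probable distribution under stoichiometric imbalance
    (Carothers' equation), chain lengths follow the standard Flory law at a
    chosen extent of reaction, and every chain is an explicit monomer
    sequence.  Chains are digested in silico at each cleavable unit and the
    resulting fragment ensembles are summarized as number-average and
    length-weighted block lengths and block-length dispersities, with
    number- and length-weighted histograms in monomer or repeat-unit scale
    and SEC-like log-scale exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
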