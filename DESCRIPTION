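Package: sgesim
Title: Individual-Based Simulation of Stochastic Gene Expression Modifier Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a diploid, two-locus
    model in which one locus is under environment-dependent viability
    selection with absorbing fitness boundaries at 0 and 1, and a second,
    freely recombining modifier locus genetically controls the magnitude of
    a Gaussian, non-heritable per-individual fitness perturbation
    (stochastic gene expression). Provides replicate-aggregated experiment
    drivers for fixation probabilities of deleterious alleles and for the
    evolutionary fate of the modifier allele under stable and fluctuating
    environments, an exact Markov-chain absorption oracle for small
    populations, parameter sweeps over selection strength, noise magnitude
    and environment-switch interval, tidy result tables, plotting methods,
    and a command-line interface with seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
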