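Package: ystar
Title: Y-Chromosome Lineage Dating and Star-Like Expansion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and dating paternal (Y-chromosome)
    genealogies from targeted resequencing read counts: a genealogy and
    read-count simulator with exact ground truth, allele-fraction genotype
    state calling with cohort coverage filters, perfect-phylogeny (binary
    maximum parsimony) tree building with tree-guided imputation of missing
    calls, strict-molecular-clock node dating with Poisson confidence
    intervals and a dispersion test of the clock, detection and Greek-letter
    naming of star-like expansions, and a tiling-uniqueness designer for
    hybridization-capture baits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
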