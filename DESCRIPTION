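Package: phylobenefit
Title: Phylogenetic Distribution of Biodiversity Benefits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse how benefits contributed by species (ecosystem
    services, uses) are distributed across a time-calibrated phylogeny.
    Implements standardized-effect-size Faith phylogenetic diversity under
    tip-draw null models, PhyloSor phylogenetic beta diversity partitioned
    into turnover and nestedness (pairwise and multiple-site, with
    tip-shuffle permutation nulls), within-genus/family compositional
    dissimilarity with non-parametric effect sizes, fair-proportion
    evolutionary distinctiveness subset tests, chi-square benefit-contribution
    tests, and a graft-then-resolve generator of tree distributions
    representing taxonomic uncertainty. Ships a synthetic-data module that
    produces labelled ultrametric trees and sparse benefit matrices with
    controllable phylogenetic structure, and a configuration-driven pipeline
    that runs the full analysis grid reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
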