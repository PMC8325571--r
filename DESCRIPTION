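Package: gexpand
Title: Phylogenetically Independent Tests of Habitat-Associated Bacterial
    Genome Size Evolution
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenomic toolkit for testing whether bacterial
    lineages that transition into a focal habitat (the human gut) evolve
    larger genomes than their closest relatives at other body sites.
    Extracts phylogenetically independent comparisons between reciprocally
    monophyletic gut and non-gut clades from an annotated phylogeny,
    polarizes them by outgroup context, computes completeness-corrected
    genome-size divergences, exact binomial sign tests, confidence
    intervals, simulation-based phylogenetic ANOVA, phylogenetically
    independent contrasts and abundance-size regressions, and enrichment
    statistics over functional score tables. Includes a fully seeded
    synthetic-cohort generator (Yule trees, continuous-time Markov habitat
    histories, trend Brownian-motion genome sizes, observation models for
    assembly completeness, abundance, MAG and enrichment tables) so every
    pipeline stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
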