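# gexpand

Comparative-phylogenomic tests of whether bacterial lineages that move
into the gut evolve larger genomes than their closest relatives at
other human body sites.

Bacteria in the human body span more than an order of magnitude in
genome size, and mean genome size differs systematically between body
sites. Two histories can produce that pattern: lineages kept an
ancestral size when they colonized their site, or evolutionary forces
drove divergence *in situ* after habitat transitions. `gexpand`
implements the comparative design that separates the two: it scans an
annotated phylogeny for **phylogenetically independent comparisons** —
pairs of reciprocally monophyletic sister clades within one genus, one
clade isolated from the gut and the other from another body site — so
that each comparison contributes a single independent observation of
habitat-associated genome-size divergence, uncontaminated by shared
ancestry.

The package is aimed at microbial comparative genomicists working with
reference-isolate phylogenies (e.g. HMP genomes) or MAG collections,
and at anyone who wants a fully seeded synthetic testbed for this class
of analysis.

## The statistics at the core

For a comparison anchored at node *N* with pure-gut child clades *G*
and pure-non-gut child clades *O*:

- clade sizes are arithmetic means over member genomes, both raw and
  **completeness-corrected** (`size × 100 / completeness`, inverting
  the expected loss of an incomplete assembly);
- divergence is summarized as the percent difference
  `100 (x̄_G − x̄_O) / x̄_O` and the log fold difference
  `ln(x̄_G / x̄_O)`;
- direction is tested with the **one-sided exact binomial sign test**
  `P = Σ_{i=k}^{n} C(n,i) (1/2)^n` over the *n* non-tied comparisons,
  of which *k* have larger gut genomes;
- comparisons are **polarized** by the anchor's sister clade: gut
  lineages nested in non-gut context carry the derived gut state
  (expansions), and vice versa (contractions);
- a simulation-based **phylogenetic ANOVA** refers the observed F
  statistic to Brownian-motion simulations on the same tree;
- genome size is related to relative abundance by polynomial
  regression per body site, by within-genus centering, and by
  regression through the origin of **phylogenetically independent
  contrasts** `(x₁ − x₂)/√(v₁ + v₂)` from Felsenstein's pruning
  algorithm;
- functional-enrichment score tables are tested with the same exact
  sign test, two-sided Fisher tests for category overrepresentation
  (e.g. CRISPR-associated families), and Benjamini–Hochberg
  correction.

A first-class synthetic-cohort generator produces every input with
known ground truth: Yule trees, continuous-time Markov habitat
histories recorded as full per-branch state paths, log genome sizes
evolving as **trend Brownian motion** (drift per unit time spent in the
gut), a uniform completeness observation model, and abundance / MAG /
enrichment tables.

## Worked example

```r
library(gexpand)

cfg    <- simulation_config(n_tips = 128, gut_trend_delta = 0.25, seed = 42)
cohort <- simulate_cohort(cfg)
report <- run_full_pipeline(cohort, seed = 42)
print(report)
```

```
Habitat genome-size divergence report
  128 tips, 15 independent congeneric comparisons
  overall: 11/15 gut larger, P = 0.0592
  mean % difference 12.82 (-2.22, 27.85)
```

11 of the 15 tip-disjoint congeneric comparisons show a larger mean
genome in the gut clade; the exact sign test gives P = 0.059 and the
mean percent difference is +12.8% (95% t interval −2.2 to +27.9) — a
small cohort simulated with a true expansion trend of 0.25 ln(bp) per
unit gut dwell time. The report carries per-stratum and per-polarity
breakdowns:

```r
report$strata[, 1:5]
##      stratum  n k_gut_larger p_one_sided mean_percent_diff
## 1    airways  2            2  0.25000000          4.627105
## 2       oral 12            9  0.07299805         15.721211
## 3 urogenital  1            0  1.00000000         -5.679772

report$regressions$per_habitat$gut
## Regression (degree 2), n = 40
##   coefficients: intercept = -9.59178, x1 = 2.45519, x2 = -0.187766
##   R^2 = 0.519, linear-coefficient P = 0.0005242
```

The gut-habitat regression recovers the generator's positive
abundance–size association (the linear coefficient is positive with
P < 0.001); non-gut habitats recover negative slopes.

The statistics also run directly on published comparison counts:

```r
sign_test(45, 59)
## Exact sign test: 45 / 59 in direction 'gut_larger', one-sided P = 3.265e-05
```

Real data enter through `read_newick()` + `read_tip_metadata()` +
`join_tree_metadata()` (Newick plus TSV), with optional
`read_abundance_table()`, `read_mag_table()` and
`read_enrichment_table()`. A thin command-line wrapper with
`simulate` / `extract` / `test` / `pic` / `abundance` / `enrich` /
`mag-compare` / `run` subcommands lives at
`inst/scripts/gexpand.R`.

## Vignette

`vignettes/habitat-genome-size.Rmd` documents the model and its
assumptions, the extraction and polarization rules, every tunable
parameter of the synthetic generator with its default and rationale,
numerical edge cases, and known limitations.
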