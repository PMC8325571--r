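---
title: "Phylogenetically independent tests of habitat-associated genome size evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically independent tests of habitat-associated genome size evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gexpand)
```

## The question and the design

Bacterial genome size varies enormously across the human microbiome,
and average sizes differ between body sites. Simply regressing genome
size on body site across species would be pseudoreplicated: closely
related species share most of their evolutionary history, so a single
ancient divergence can masquerade as dozens of independent
observations. The comparative design implemented here avoids that by
extracting **phylogenetically independent comparisons**: tip-disjoint
pairs of sister clades within one genus in which the gut-isolated
lineages and the lineages from other body sites are reciprocally
monophyletic. Each pair contributes exactly one observation — did the
gut clade end up with a larger mean genome than its closest non-gut
relatives? — and directions are aggregated with an exact binomial sign
test.

## Extraction: the anchor rule

An internal node anchors a comparison if and only if **every** child
subtree is habitat-pure (entirely gut or entirely non-gut), with at
least one pure-gut and one pure-non-gut child; pure-gut children are
pooled into the gut side, the rest into the other side. For the
congeneric level all tips under the anchor must share one genus; the
conspecific level additionally requires a shared species label.

Three properties motivated this operationalization of reciprocal
monophyly:

* *Automatic independence.* An anchor's subtree is habitat-mixed, so no
  ancestor of an anchor can anchor — emitted comparisons are
  tip-disjoint by construction, with no post-hoc pruning step.
* *Determinism at multifurcations.* Polytomies are handled by the
  pooling rule, never by random resolution, so the comparison set is a
  pure function of the tree and its annotations.
* *A checkable contract.* The rule is a per-node predicate, so the
  whole traversal is verified in the test suite against brute-force
  evaluation of the predicate at every internal node of hundreds of
  random trees.

A node with a habitat-mixed child does **not** anchor even if its other
children would qualify; the comparison then forms deeper inside the
mixed subtree. This is the conservative reading — it never manufactures
a comparison that straddles an unresolved habitat boundary.

## Polarization

To separate expansions in the gut from contractions outside it, each
comparison is polarized by the habitats found in the sister clade(s) of
its anchor (the other children of the anchor's parent): all non-gut
sister tips mean the gut state is derived (candidate expansion), all
gut means the non-gut state is derived (candidate contraction), and a
mixed sister context — or an anchor at the root — leaves the comparison
unpolarized. Unanimity of the immediate sister clade is a deliberately
conservative parsimony criterion: it uses only one node of outgroup
context, never propagates an uncertain deeper reconstruction, and
ambiguous cases are retained in the comparison table but excluded from
polarity-conditioned tests. Contraction tests use the same exact upper
tail with the direction reversed (k counts comparisons with smaller gut
genomes).

## Divergence measures and their null behaviour

Clade size is the arithmetic mean over member genomes. Both raw
assembly sizes and completeness-corrected sizes
(`size × 100 / completeness`) are always carried side by side; the
correction undoes the expected underestimate of an incomplete assembly
and is exact for the uniform observation model used by the generator
(inverted to within 1 bp of rounding).

Two divergence scales are reported per comparison:

* the **percent difference** `100 (x̄_G − x̄_O) / x̄_O`, the intuitive
  effect size; note that as a ratio statistic it carries a small
  positive Jensen bias under the exchangeable null (the expectation of
  `X/Y` exceeds 1 for i.i.d. positive `X`, `Y`), so its null mean is
  slightly above zero even when direction is perfectly symmetric;
* the **log fold difference** `ln(x̄_G / x̄_O)` (base configurable to
  2), which is antisymmetric under swapping the clades and therefore
  exactly mean-zero under the null. Calibration checks in the test
  suite assert centering on this scale, and direction-based inference
  (the sign test) is immune to the ratio bias entirely.

Exact ties in clade means are flagged and dropped from sign-test
denominators — they are measure-zero for real assemblies but arise in
constructed fixtures.

The sign test is the exact binomial upper tail computed by summation
(`pbinom`), never a normal approximation; the suite verifies it against
enumeration of all `2^n` outcomes up to n = 15. Confidence intervals
for mean percent differences default to the two-sided 95% Student t
interval; a seeded percentile bootstrap (default 10,000 resamples) is
available where the t assumption is unwanted. The choice of interval
is not prescribed by the comparative design itself, so both are
exposed.

Strata: each comparison is assigned to the habitat of its non-gut side
when that side is pure, and to `"mixed"` otherwise, mirroring how
oral-vs-gut or urogenital-vs-gut contrasts are counted as separate
strata.

The unanimous-minority **pattern probability** `(1 − q)^m` answers a
narrow question: if a fraction `q` of comparisons fall one way, what is
the chance that `m` flagged comparisons (here, lineages under foodborne
pathogen surveillance) all fall the other way by luck alone.

## Phylogenetic ANOVA

The observed statistic is the ordinary one-way ANOVA F of tip values by
group. Its reference distribution comes from Brownian-motion
simulations on the same tree: the F statistic is scale-free, so the
simulated null depends only on the tree and the grouping, and the
p-value is `(1 + #{F_sim ≥ F_obs}) / (1 + n_sim)` — the add-one form
that can never report zero. The Brownian rate is still estimated (as
the mean squared standardized contrast) and recorded for transparency.
Polytomies are resolved deterministically (zero-length branches,
tip-label order) for the contrast-based rate estimate only; the
simulation works on the original topology through the tip × edge
incidence of root paths, which needs no resolution. Groups require at
least two tips each; a constant trait yields F = 0 by convention and a
p-value near 1.

## Contrasts and regressions

Independent contrasts follow the standard pruning recursion:
`(x₁ − x₂)/√(v₁ + v₂)` at each join, weighted-average nodal values,
and branch lengthening `v₁v₂/(v₁ + v₂)`. Two conventions are fixed so
results are bit-reproducible: children are folded in order of their
smallest descendant tip label (zero-length resolving branches at
polytomies), and the contrast sign is first-minus-second in that
order. A node whose two adjusted lengths are both zero has no
information about the contrast and is an error rather than a silent
0/0.

Contrast regression is least squares **through the origin** — contrast
signs are arbitrary, so the model must be odd — with the uncentered R²
and a t test on the slope. The slope is algebraically identical to the
generalized-least-squares slope under the Brownian covariance with an
intercept, and the package ships that GLS computation as an independent
oracle (`pic_regression_oracle_gls`); the equality is asserted to 1e-8
on a thousand random trees in the suite. A two-contrast regression has
a defined slope but no residual degree of freedom for the t test, so
its p-value is NA.

Tip-level abundance regressions keep their intercept and default to
polynomial degree 2: abundance–size relationships are typically curved,
and inference is reported for the linear coefficient. Relative
abundances are log10-transformed after dropping zeros (half-minimum
imputation available) — the floor choice only shifts intercepts.
Within-genus association is estimated by centering both variables on
genus means and pooling, which uses only within-genus variation;
genera with fewer than two species carry no such information and are
dropped. Centering was chosen over genus fixed effects as the two give
identical slopes here and centering keeps the result a single ordinary
regression.

## Enrichment statistics

Enrichment scores are an input table (their computation from pangenomes
is out of scope). Direction is tested with the same exact sign test on
the nonzero scores; category overrepresentation (e.g. CRISPR-flagged
families among positively enriched ones, against zero-score families as
the reference) uses the two-sided Fisher exact test with the
minimum-likelihood convention; multiple testing uses Benjamini–Hochberg.
All three are verified against independent oracles (exhaustive
fixed-margin enumeration for Fisher; step-up arithmetic for BH). Note
that BH re-adjustment is not the identity in general, so adjusted
values should not be fed back through the procedure.

## The synthetic cohort: what it emulates

`simulation_config()` fixes the study conditions; all defaults were set
once, from the biology being emulated, and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `n_tips` | 512 | desk-scale stand-in for a reference-isolate phylogeny of thousands of genomes |
| `birth_rate` | 1 | Yule tree; time is in units of expected branch length |
| `rate_matrix` | to gut 0.25, from gut 0.25, between non-gut sites 0.02 | switching frequent enough that one cohort yields independent-comparison counts on the order of the ~59 of the real reference phylogeny, the regime in which the discrete sign test operates near its nominal level |
| `root_log_size` | ln(3 Mb) | typical bacterial genome |
| `bm_sigma2` | 0.02 /unit time | several-fold neutral size variation across the tree, matching the >10-fold spread among body-site bacteria |
| `gut_trend_delta` | 0.25 ln(bp)/unit gut time | a moderate, clearly detectable expansion trend; 0 is the null |
| `completeness_range` | 90–100% | mirrors the >90%-complete quality filter applied to real assemblies |
| `abundance_params` | gut slope +0.5/Mb, others −0.5/Mb, host sd 0.5 | sign structure of the observed abundance–size associations |
| `abundance_species_sd` | 1 (log10) | species-level scatter dominates the species-mean regression, keeping R² in a realistic range rather than near 1 |
| `genus_depth_frac`, `species_depth_frac` | 0.6, 0.88 | genera and species as depth cuts; a modeling convenience, documented as such |
| `pathogen_rate` | 0.05 per genus | a handful of flagged lineage sets per cohort |

Habitat evolution is simulated as a continuous-time Markov chain with
the **full state path recorded per branch**, because the size model
needs dwell times, not just node states: log size evolves as Brownian
motion plus a deterministic drift per unit of time spent in the gut
state ("trend BM"). This models expansion as an in-situ evolutionary
tendency rather than an instantaneous jump at colonization; a
point-shift alternative (`shift_at_transition`) is provided for
sensitivity analysis. Every stage draws from its own substream derived
from the master seed, so cohorts are bit-reproducible and stages can be
re-run in isolation.

What the generator does **not** emulate — and what green tests
therefore cannot certify about real data: horizontal transfer and
recombination, assembly contamination biasing size upward, correlated
errors between completeness and size, non-uniform taxon sampling,
compositional coupling beyond per-sample closure of abundances, and
habitat assignment error in metadata. The generator answers "does the
pipeline recover known truth under its own model", nothing stronger.

## Validation scale and numerical choices

The suite validates at sizes chosen to balance statistical resolution
against a single-CPU run of a few minutes: 500 replicate cohorts for
null calibration (pooled direction fraction, rejection rate at α =
0.05, and — because the exact test is discrete — a rejection rate
expected slightly *below* 0.05), 150 replicates per point of the
expansion-trend grid {0, 0.1, 0.25, 0.5}, 100 replicate cohorts for
abundance-slope sign recovery at 200 species per habitat, and 500
Brownian null replicates for the uniformity of the phylogenetic-ANOVA
p-value. Oracle equivalences are exhaustive where feasible (all `2^n`
sign-test outcomes to n = 15; all fixed-margin Fisher tables to total
60) and randomized elsewhere (1,000 trees for the PIC/GLS identity at
1e-8).

Other numerical conventions: branch lengths may be zero but never
negative; Newick output carries 12 significant digits so read∘write is
the identity at working precision; habitat labels are normalized
case-insensitively onto a closed six-value vocabulary with unknown
sites mapped to `"other"` under a warning (custom aliases supported);
metadata joins must be exact bijections — the pipeline refuses partial
joins rather than silently dropping tips.

## Limitations

* Polarization uses one node of outgroup context; deeper ancestral
  reconstruction could polarize more comparisons at the cost of model
  assumptions.
* The trend-BM generator is one of many plausible expansion models; the
  point-shift mode is the only built-in alternative.
* MAG species-bin comparisons assume independence across bins and use
  no within-species tree.
* Branch lengths are taken as given and unit-agnostic; nothing here
  infers trees or calibrates time.
* The percent-difference summary is reported because it is the familiar
  effect size, but its ratio bias means averages of it should be read
  alongside the log-fold scale.
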