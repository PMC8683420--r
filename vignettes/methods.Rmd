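---
title: "Methods: phylogenetic structure of biodiversity benefits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic structure of biodiversity benefits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `phylobenefit`, the
choices made where the methods literature leaves room, and what the
synthetic testbed does and does not establish.

## Data model

Three objects drive every analysis: a rooted, ultrametric, time-calibrated
phylogeny (an `ape` `phylo`, branch lengths in Myr); a binary species ×
benefit incidence matrix (`benefit_matrix`, rows restricted to taxa with at
least one benefit, as in real use tables); and a `taxonomy_map` from tip to
genus to family, with every genus in exactly one family. Analyses that
accommodate phylogenetic uncertainty take a `tree_distribution`, an ordered
set of trees sharing a tip-label set; per-tree statistics are aggregated as
mean ± 95% CI.

## Alpha diversity: SES of Faith's PD

Faith's PD of a tip set is the summed branch length of the union of the
tips' root paths. **Root inclusion is a convention, not a fact**: published
analyses rarely state whether the path from the set's MRCA up to the root is
counted. Both conventions are implemented (`include_root`); the default is
root-inclusive, matching the common behaviour of the field's tooling, and
the two differ only by the root-to-MRCA path. All internal PD work is done
on an edge × tip incidence matrix, which lets the null draws be evaluated as
one matrix product rather than per-draw traversals.

The null model draws `n_null` uniform, without-replacement tip samples of
the focal size from a pool (all tips by default; the beneficial pool is used
where the question demands it), and

SES = (M_obs − M_null) / SD_null,

with the sample (n − 1) standard deviation — fixed as a convention so that
oracle tests can recompute SES exactly from the stored null values.
`n_null = 999` is the conventional default; functions accept anything ≥ 99.
A focal set that exhausts its pool yields SD_null = 0 and is returned
flagged degenerate rather than as an error, because it is a legitimate
boundary of the design (e.g. "all beneficial species" against the
beneficial pool).

Per-tree SES values are aggregated as mean ± 1.96·sd/√n (a percentile CI is
available behind `ci_method`; which of the two a given published analysis
used is generally unstated, so the default is documented rather than claimed
canonical). A significance call at nominal alpha is made only when the whole
CI clears the two-tailed standard-normal threshold (±1.96 at 0.05): this is
deliberately conservative under phylogenetic uncertainty — a single
ambiguous tree can withhold a call.

Within a tree distribution the null-draw seed is reset per tree, so two
identical trees give identical SES and the spread across the distribution
reflects phylogenetic uncertainty only, not Monte-Carlo noise.

## Beta diversity: PhyloSor partition and nulls

For two tip sets with shared ancestral branch length `a` and unique lengths
`b` and `c` (computed under the same root convention as PD):

- pβ_sor = (b + c) / (2a + b + c) — total dissimilarity (1 − PhyloSor);
- pβ_sim = min(b, c) / (a + min(b, c)) — true turnover, insensitive to PD
  differences;
- pβ_nes = pβ_sor − pβ_sim — the nestedness-driven remainder.

Degenerate inputs (a = b = c = 0, only possible for coincident singleton
paths under the root-exclusive convention) are defined as zero dissimilarity.
The taxonomic (Sørensen) version replaces branch lengths with set
cardinalities. The multiple-site generalization uses the Sørensen-family
partition over pooled and pairwise unique components; with two sites it
reduces exactly to the pairwise form, and the test suite anchors it to
brute-force evaluation of the formulas on 3-site instances (ties in
min/max need no special handling: when b_ij = b_ji, min = max).

The turnover null shuffles taxon labels **across the beneficial tips only**
(an all-tips mode exists for sensitivity checks): compositional structure —
carrier counts and their overlap — is preserved exactly, while phylogenetic
positions are randomized. Permutations are evaluated in bulk against the
incidence matrix, so 999 permutations cost two matrix products.

Within genera and families, species are treated as sites and benefits as
species; clades with fewer than two beneficial members are excluded (two
sites are required). Because the null distributions of within-clade
dissimilarities are typically far from normal (strongly discrete for small
clades), effect sizes use the non-parametric

P = [#(null < obs) + #(null = obs)/2] / (n_null + 1),  ES = 2(P − 0.5).

The published form of the denominator is the constant 1000 for 999 nulls;
it is generalized here to n_null + 1 so the null count is configurable
without changing the edge-case values (0.998, −1, −0.001 for
all-below/all-above/all-tied at 999 nulls).

## Evolutionary distinctiveness

Fair-proportion ED divides each branch length equally among its descendant
tips; tip scores sum to the total branch length (a conservation identity
asserted to 1e−9 relative in the tests; any root edge is ignored). Subset
tests use the **median** ED, because ED distributions are strongly
right-skewed by a few extreme values; the median of an even-sized set is the
mean of the two central values. Nulls are size-matched draws from either the
entire phylogeny or the beneficial pool, drawn independently per tree
(medians are cheap; nothing is reused across trees). Chi-square
benefit-contribution tests use the two-cell construction per benefit —
(x, N − x) against (pN, (1 − p)N), df = 1 — which is the direct encoding of
"contributions in proportion to representation"; a 2 × 2 records table is a
defensible alternative reading, and the choice is documented rather than
asserted. Expected cells below 5 are flagged, and Bonferroni/BH columns are
emitted without being used for calls, matching per-type reporting practice.

## Trees under taxonomic uncertainty

`graft_taxon()` attaches an unplaced taxon at a point chosen uniformly
(length-weighted) along the branches of its constraint clade. The clade's
stem branch is included by default — "the clade that most certainly
contains it" is read as crown-or-stem membership — with a crown-only flag.
`expand_genus_tips()` replaces each genus tip by a pure-birth (Yule)
subtree; the pure-birth rate is irrelevant after rescaling and fixed at 1.
**Where the genus crown sits below the genus stem is not specified by any
rule we can point to**, so it is an explicit parameter: `crown_fraction`
(default 0.5) of the genus terminal branch lies below the crown. All
expansions and grafts preserve existing tip depths exactly, so
ultrametricity (checked at relative tolerance 1e−6, a warning rather than
an error, since published calibrated trees carry rounding noise) is
maintained by construction. Distribution building derives one RNG sub-seed
per (base tree, replicate), so any member can be regenerated in isolation.

## The synthetic testbed

The default scenario is 8 families × 5 genera × 5 species (200 tips, depth
100 Myr). A Yule backbone over families is rescaled to full depth; family
and genus crowns each sit at half their stem's terminal branch
(`family_crown_fraction = genus_crown_fraction = 0.5`), giving deep family
stems and shallow species crowns — the geometry in which clustering and
overdispersion of benefit carriers are phylogenetically meaningful. Six
benefits are assigned at sparse prevalences (10–15% of species), two each
by the clustered, random and overdispersed rules; most beneficial species
end up with one or two benefits, as in real use tables. Clustered
assignment fills the patristic neighbourhood of a random seed tip (ties
broken by label order, so assignment is deterministic per seed);
overdispersed assignment is greedy farthest-point selection, which on a
balanced tree with dominant family stems picks one representative per
family.

Injection of multi-beneficial, evolutionarily distinct species gives
`count = 8` species `benefits_each = 5` benefits and multiplies their
terminal branches by `stretch = 4`, reattaching each tip deeper along its
own ancestral path (depths of all other tips unchanged). Because a
multiplicative stretch of a near-zero terminal cannot produce a long
branch, the injected species are the ones with the longest stretchable
terminals among the beneficial set — the point of the module is precisely
to create long-branch multi-beneficial species. In multi-tree scenarios
the same species are stretched in every member.

What the testbed does **not** emulate: real prevalence spectra across 25
benefit categories, correlated benefit assignment (real benefits co-occur
non-randomly), non-ultrametric measurement error, or megaphylogeny scale.
Passing parameter recovery therefore shows the statistics detect the
structures they are defined to detect at realistic effect sizes — not that
any particular empirical dataset has those structures.

## Problem sizes and calibration checks

The test suite and acceptance script use sizes chosen to make every check
sharp but quick: brute-force oracles on ≥ 100 random trees of ≤ 12 tips;
type-I calibration of SES-PD and SES-pβ_sim on a 64-tip Yule tree (focal
sizes 10–12, 999 nulls, 500 replicates) and of the median-ED test on a
200-tip tree (subsets of 25 — medians of very small subsets are discrete
enough to distort nominal rates, so the calibration uses a subset size in
the regime the battery actually operates in); parameter recovery over 20
seeded replicates of 10-tree scenario distributions with 199 nulls per
tree. Rejection rates at |SES| > 1.96 are required to sit within 99%
binomial bounds of 0.05.

## Known limitations

- Patristic-distance rules (`assign_benefit`) build a full cophenetic
  matrix: fine to a few thousand tips, not for megaphylogenies.
- The pairwise turnover SES matrix is quadratic in the number of benefit
  types; `run_beta_pairs` can switch it off in the pipeline.
- `capture_probability()` is exact enumeration and guards itself above
  2 × 10⁶ combinations; it is a toy-scale tool by design.
- The genus-grain view in the pipeline represents each genus by one of its
  species pruned from the species tree; when a dedicated genus-level
  phylogeny exists it should be supplied directly instead.
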