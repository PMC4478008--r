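---
title: "Phylogenetic trait imputation and trait-based biogeography with traitscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic trait imputation and trait-based biogeography with traitscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitscape)
```

## The problem

Functional traits are measured for only a small minority of microbial
lineages. When a marker-gene phylogeny (here, the ketosynthase-alpha gene of
type II polyketide synthase clusters, whose products include spore pigments
and many aromatic polyketide antibiotics) contains a few dozen *reference*
tips whose product is structurally characterized alongside thousands of
*environmental* tips, the trait of each environmental sequence can be
predicted probabilistically from its phylogenetic neighborhood. traitscape
implements this hidden-state prediction and the downstream community
analyses: trait pseudo-abundance matrices, tree-based sequence-group binning,
three layers of beta-diversity, distance-decay and driver statistics, and a
phylogenetic trait-clustering test.

## The model

Traits evolve on the tree under a continuous-time Markov ("Mk") model with
*equal rates*: for `k` trait states the rate matrix has every off-diagonal
entry equal to a single rate `q` (per ordered state pair) and diagonal
`-(k-1)q`. The transition probabilities over a branch of length `t` have the
closed form

$$P_{ii}(t) = \tfrac1k + \tfrac{k-1}{k} e^{-kqt}, \qquad
  P_{ij}(t) = \tfrac1k\left(1 - e^{-kqt}\right),$$

which the implementation uses directly instead of a generic matrix
exponential (the test suite verifies both agree to 1e-12). Likelihoods are
computed by Felsenstein's post-order pruning with per-node rescaling so trees
with thousands of tips do not underflow; a missing tip contributes a vector
of ones and marginalises out exactly. The root prior is uniform, which for
the equal-rates model is also the stationary distribution; under this
time-reversible setup the likelihood and all tip marginals are invariant to
the rooting (a property the tests check to 1e-10).

## Imputing a tip trait

For a query tip `estimate_tip_trait()`:

1. prunes the tree to the query plus all annotated references, suppressing
   unifurcations and summing merged branch lengths;
2. reroots the pruned tree at the query's parent (the ancestor of the query
   and its closest relative);
3. fits `q` by bounded 1-D maximum likelihood on the reference states with
   the query treated as missing;
4. computes the marginal state distribution at the new root from the
   reference data; and
5. propagates that distribution across the query's pendant branch.

Because the missing query marginalises out of the likelihood, the rate fit in
step 3 equals the reference-only fit; batch operations therefore fit the rate
once per tree and trait field and reuse it — an exact identity, not an
approximation. Steps 4–5 likewise equal the missing-data marginal at the
query tip on the unrerooted tree; the tests assert this equivalence against
a brute-force enumeration oracle to 1e-8.

Two thresholds matter downstream, both exposed as configuration keys:

* **0.5** — a query whose probability of encoding spore pigmentation exceeds
  0.5 is excluded before antibiotic chemotype analyses
  (`classify_spore_pigment()`);
* **0.75** — a chemotype assignment is called *confident* when the modal
  probability reaches 0.75 (`assign_chemotypes()`).

The rate search interval defaults to `[1e-8, 100]` with tolerance 1e-8 on
`q`; the likelihood is unimodal in this 1-D problem, so a deterministic
bounded search suffices and no random restarts are used. Estimates within
1e-6 of a bound are flagged `at_bound` (monotone likelihoods arise when
references are uninformative, e.g. two identical or two maximally different
reference states).

## Trait clustering on the phylogeny

Whether a chemotype is phylogenetically clustered — the premise that makes
imputation informative — is tested by comparing the Faith's PD spanned by
the tips carrying the trait against 10,000 uniform draws of the same number
of tips (`trait_clustering_score()`). The reported statistic is the rank of
the observed PD among the draws divided by draws + 1; ties count as at or
below the observed value, which is conservative toward non-clustering. The
field often labels this rank quantile a "z-score" and the output keeps that
label for traceability. PD is measured below the MRCA of the set with the
root path excluded by default (`pd_include_root_path` switches this; the
convention is not standardized).

## Sequence groups, rarefaction and the trait matrix

Sequence similarity groups are *maximal clades whose members are pairwise at
least x% identical* — the furthest-neighbor criterion applied along the
tree, so groups never span clades even when sequences are similar. Percent
identity is computed on the input alignment: columns where both sequences
have gaps are excluded, columns where exactly one has a gap count as
mismatches (a configuration switch excludes them instead), and `N` matches
nothing. Samples are rarefied without replacement to a common depth (the
minimum across samples by default), with one RNG substream per sample
derived by hashing the sample id so results do not depend on sample order.
The trait community matrix is the product of the rarefied presence matrix
with the per-sequence trait probability matrix, conserving each sample's
total count.

## Beta-diversity layers and driver statistics

Three dissimilarity layers are compared on identical sample sets:
Bray–Curtis on sequence groups, normalized weighted UniFrac on the
phylogeny (each branch weighted by the absolute difference in the relative
abundance descending from it, normalized by the fully-disjoint score so
values lie in [0, 1]), and Bray–Curtis on the trait pseudo-abundances.
Distance decay is quantified by Mantel tests (999 permutations by default)
with the slope of log10 dissimilarity on log10 geographic distance;
sampling designs that start at centimetres produce zero distances, so pairs
at exactly zero are excluded from log-log fits and positive distances below
a 0.01 m floor are floored (`distance_floor`). The 95% slope interval is a
randomization interval obtained by residual randomization in the same
permutation stream. Partial Mantel tests and multiple regression on distance
matrices (response-matrix permutation, coefficients refit, two-sided on the
absolute coefficient with +1 smoothing) attribute turnover to geography,
environment and plant composition; p-values across one driver run are also
reported Bonferroni-adjusted. Environmental variables are min-max scaled to
[0, 1]; pairs with squared correlation at or above 0.7 are pruned (keeping
the earlier variable in input order) before an exhaustive `bioenv()` search
selects the subset whose Euclidean distance best rank-correlates with
community dissimilarity. Mantel correlations default to Pearson (a Spearman
flag is provided, as the convention differs between implementations). The
plant-community dissimilarity uses Jaccard on presence/absence.

## The synthetic landscape

`simulate_landscape()` generates the study conditions the analyses assume:
three continents with 50 samples each, a within-continent extent of 170 km
(sample pairs spanning sub-metre to full-extent separations via clustered
placement with lognormal jitter), intercontinental separations of thousands
of kilometres, a unit-height pure-birth gene tree, a spore-pigment clade
(about 5% of tips), 20 antibiotic chemotypes assigned to 90%-identity
clades so that each chemotype occupies about 3 distinct sequence groups
(trait convergence — distinct evolutionary origins of the same chemistry),
and about 20% of tips annotated as references, stratified so every label is
represented. Sequence occurrence probability decays exponentially with the
distance from a home location (rate `decay_lambda`, default 3e-5 per metre)
and is down-weighted off the home continent, giving distance decay and
continental clustering; environmental variables and plant presences share
the spatial gradient. Percent identity is derived from patristic distance
through the monotone map `100 * exp(-d/2)` — full sequence simulation
(Jukes–Cantor along the tree) is available when an explicit alignment is
needed. The tree size defaults to 400 sequences: large enough that roughly
80 references span 20 chemotypes, the regime the method targets, while
keeping a full landscape replicate in the low seconds.

What the generator deliberately does not emulate: alignment error and rate
heterogeneity across sites or lineages, PKS copy-number variation, primer
bias, and chimeric sequences. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to those
artefacts.

## Numerical choices and degenerate inputs

* Zero-length branches give an identity transition matrix; negative branch
  lengths are rejected at I/O.
* Trait probability rows must sum to 1 within 1e-9 (enforced on
  construction); distance matrices must be symmetric with zero diagonals.
* A query equidistant from two equally labelled neighborhoods returns equal
  probabilities to 1e-9 (ties in `max.col` resolve to the first label only
  for the cached modal label, never the probabilities).
* When every reference shares one label the estimation errors out rather
  than returning a degenerate certainty.
* The binning collapse at cutoff 100 leaves only exact-duplicate clades
  grouped; as the cutoff decreases group counts are non-increasing and
  groups form a nested refinement chain (tested).
* ANOSIM is delegated to vegan; Bray–Curtis and Jaccard to `vegan::vegdist`;
  great-circle distances to geosphere. The Mk pruning machinery, tip
  imputation, Faith's PD, the clustering test, binning, rarefaction,
  weighted UniFrac, Mantel/MRM/bioenv are implemented in the package, with
  picante, vegan and Matrix used as independent cross-checks in the tests.

## Problem sizes used by the test suite

The suite verifies exact oracles on small instances (trees of up to 8 tips
against exhaustive enumeration; hand-summed UniFrac and Bray–Curtis
examples) and statistical behaviour at moderate scale: rate recovery on a
200-tip tree over 50 trait replicates, a 625-sequence / 20-chemotype
calibration benchmark with about 500 queries, 500-replicate null
distributions for the PD quantile and the Mantel level, and 20 replicate
landscapes for the ordering of the three beta-diversity layers. These sizes
were chosen as the smallest at which the statistical claims are
well-resolved.

## Worked example

```{r example, eval = FALSE}
L <- simulate_landscape(landscape_config(seed = 1))
queries <- setdiff(colnames(L$community), L$refs$id)

# spore-pigment filtering, then chemotype probabilities
pig <- classify_spore_pigment(L$tree, L$refs, queries)
retained <- setdiff(queries, attr(pig, "excluded"))
ch <- assign_chemotypes(L$tree, L$refs, retained)
summary(ch)[1:3, ]

# community layers on rarefied samples
rare <- rarefy(L$community[, retained], min(rowSums(L$community[, retained])))
d_group <- bray_curtis(collapse_to_groups(rare, L$groups))
d_phylo <- weighted_unifrac(rare, L$tree)
d_trait <- bray_curtis(build_trait_matrix(rare, ch))

# distance decay of the trait layer
mantel(geo_distance(L$meta)[rownames(rare), rownames(rare)], d_trait,
       n_perm = 999, seed = 1, loglog_slope = TRUE)
```

Or run everything at once from a configuration:

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(tree = L$tree, alignment = L$identity, refs = L$refs,
                       community = L$community, metadata = L$meta,
                       out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
res$summary$mean_dissimilarity
```

## Known limitations

* The equal-rates model is the only Mk variant offered; all-rates-different
  and branch-heterogeneous models are out of scope, as are joint (rather
  than marginal) reconstructions.
* Sequence groups from the tree can split identical sequences that sit in
  different clades — a documented property of the clade-respecting collapse.
* The MRM permutation scheme permutes the response matrix; permuting
  residuals is a defensible alternative the package does not implement.
* Trait probabilities shrink toward uniform as reference density falls;
  community-level trait dissimilarities are correspondingly compressed, so
  comparisons across datasets with very different reference coverage should
  be read with care.
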