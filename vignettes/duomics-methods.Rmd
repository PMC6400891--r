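---
title: "Methods: integrating transcriptome and proteome differential expression"
author: "duomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating transcriptome and proteome differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duomics)
```

## Scope and design

`duomics` implements the analysis stack used to ask whether a photoreceptor
mutation rewires gene expression at both the transcript and the protein
level in a 2 (genotype) x 2 (light condition) factorial seedling
experiment: consensus RNA-seq differential-expression (DE) calling,
2D-gel spot quantification, permutation tests for the overlap of
differentially expressed protein (DEP) and transcript (DET) sets,
a weighted co-expression network with module eigengenes, Fisher's-exact GO
enrichment, and qPCR relative quantification. A synthetic-data generator
emulates the full study design with planted ground truth, so every stage
can be exercised and validated without any external data.

The package is tidyverse-native: tabular interfaces take a data frame whose
first column identifies the feature (`gene`, `spot`, `gel`) and return
tibbles; fitted results support `tidy()`, `glance()` and `autoplot()`.
The square gene-by-gene similarity objects (adjacency, topological overlap)
are plain matrices, because that is what they are.

## The synthetic study

`study_design()` encodes the design the pipeline is organized around:
two genotypes (wild type coded 0, mutant coded 1), two light conditions
(dark 0, red 1), four RNA-seq replicates per group (16 samples) and six
gels per group (24 gels) for proteomics.

`simulate_counts()` draws negative-binomial counts with
`variance = mu + alpha mu^2`. Per-gene log2 means combine:

* a log-normal baseline (`meanlog = log(100)`, `sdlog = 1.5`), giving the
  heavy-tailed abundance distribution typical of bulk RNA-seq;
* planted DE blocks for genotype, light and their interaction, with
  alternating signs and default |log2FC| of 3, 3 and 2 — the scale of the
  strong responses the pipeline is meant to recover at four replicates per
  group (a BH threshold across ~24,000 genes demands raw p ~ 1e-3, so
  planted two-fold changes at median depth would sit at the detection
  boundary rather than above it);
* twelve latent-factor modules. Each module has one per-sample latent
  profile; a gene's expression adds `loading * profile` with loadings
  uniform on [0.8, 1.4] and "core" genes (10% of each module) at twice the
  background loading. A module's profile mixes its driving covariate
  (genotype, condition, interaction, or none) with a module-specific
  component in proportions set by a per-module trait strength
  (0.95/0.70 per trait by default), and amplitude 3 log2 units.

Two properties of the module model are deliberate. First, the
module-specific component is orthogonalized within genotype-by-condition
groups, so the systematic group shift of a module gene is exactly
`loading * amplitude * strength` and the planted answer key is exact.
Second, two modules driven by the same covariate are distinguishable only
through their module-specific components; their eigengene correlation
approaches the product of their trait strengths, which the defaults keep
below the merge threshold. A consequence worth understanding when reading
test results: genes in a trait-driven module carry shared within-group
noise (sd `0.5 * amplitude * sqrt(1 - strength^2)` per sample), which is
genuine biological co-variation and intrinsically limits their single-gene
detectability. The generator therefore reports two answer keys:
`truth$de_genes` (the clean DE blocks, used for sensitivity) and
`truth$trait_responsive` (everything with any planted group effect,
used when counting false positives).

The generator does not emulate several features of real data: no
gene length or GC effects, no batch structure, no outlier samples, no
zero-inflation beyond what the NB gives, and module co-variation is rank
one per module. Passing recovery tests on this generator therefore shows
the pipeline's logic is correct under its stated noise model, not that the
pipeline is robust to everything real data does.

`simulate_spot_volumes()` produces log-normal gel-by-spot volumes (218
spots by default, residual sd 0.29 on the log2 scale, i.e. ~20% CV) with
per-gel intensity factors that the normalization must remove, and a
many-to-one spot-to-gene map (35% duplicated identifiers by default),
mirroring how one protein appears as several proteolytic or modified
spots. When given the RNA truth, a configurable fraction (default 0.6) of
the planted genotype-effect spots take the sign opposite to their gene's
transcript effect — the transcript/protein discordance motif.

`simulate_go_annotation()` samples term memberships uniformly except for
planted enriched terms, which over-sample a designated study set at a
stated odds ratio. `simulate_ortholog_map()` builds a partial one-to-one
map between two label universes, emulating reciprocal-best-hit ortholog
tables.

All generators are pure functions of their configuration and seed.

## Consensus differential expression

Counts are normalized with median-of-ratios size factors (the reference
gene set is genes with positive counts in all samples; an explicit
pseudo-reference fallback exists for degenerate matrices). Per-gene NB
dispersions are method-of-moments estimates pooled within groups, blended
on the log scale (weight 0.5) with a fitted `a0 + a1/mean` trend and
floored at 1e-4; genes with no observable over-dispersion sit at the
floor.

Three deliberately distinct callers are provided:

* `nb_wald`: per-gene NB log-linear model with size-factor offset and the
  trend-shrunk dispersion; the Wald statistic is divided by the root
  quasi-dispersion (residual deviance / residual df) and referred to a t
  distribution on n - 2 df. With four replicates per group the plain
  normal-reference Wald rejects ~7% at nominal 5% and the unscaled t(6)
  version ~3%; the quasi-likelihood form sits at ~5% across null
  simulations, which is why it is the shipped form.
* `nb_lrt`: likelihood-ratio test of the group term in the same model,
  with a Bartlett-type `(n - p)/n` deviance scaling chosen for the same
  calibration reason.
* `logt`: pooled-variance t-test on `log2(normalized + 1)` — a
  transform-based caller methodologically unrelated to the NB pair. It
  stands in for an alignment-based third method, which cannot operate on a
  count matrix; this divergence is intentional and documented.

P-values are Benjamini–Hochberg adjusted within each contrast ("corrected
p-value" is read as BH, the default of the packages this emulates). The
consensus rule (`consensus_calls()`) includes a gene only if at least
`min_methods = 2` of the callers flag it at q < 0.05 within *every*
read-mapper group — the strictest reading of "regardless of mapping
strategy"; a union mode and a single-group degenerate case are supported —
and only if its identifier exists in the declared universe.

## 2D-gel proteomics

Spot volumes are divided by their gel's total volume
(`relative_spot_volumes()`), which removes per-gel staining and loading
scale exactly; rows then sum to one. Differential spots use a
pooled-variance Student t-test (the named test; two-sided, the
conservative default where sidedness is unstated) at raw p < 0.01 with
**no multiple-testing correction across spots** — this mirrors standard
2D-gel practice and is highlighted because it differs from the RNA side.
`collapse_spots_to_genes()` maps significant spots through the
many-to-one spot map and reports the redundancy accounting (total calls,
non-redundant spots across comparisons, unique gene identifiers, unmapped
spots), the structure used when cross-referencing DEP and DET sets.

## Overlap permutation tests

The central integration statistic: draw `n_a` items from universe A
(spots, or a mapped ortholog set) and `n_b` from universe B (genes),
translate the A draw through the item-to-gene map, and count distinct
shared gene identifiers; repeat (10,000 permutations by default) and
report the upper-tail p for the observed overlap.

Two p-value conventions are implemented. The default
`(exceedances + 1) / (n_perm + 1)` is a valid permutation p that can never
be zero. The `raw` convention reports the plain exceedance proportion
floored at `1/n_perm`, matching the style in which a zero-exceedance
result at 10,000 permutations is printed as 0.0001 — and in which an
observed overlap of 0 prints exactly p = 1.0.

When the item-to-gene map is one-to-one the null overlap is exactly
hypergeometric, and `analytic_overlap_p()` (a `phyper` tail) serves as an
independent oracle; the test suite checks agreement over a grid of
specifications within three Monte-Carlo standard errors. With a
many-to-one map the null shifts: drawing duplicated spots yields fewer
distinct identifiers, lowering the overlap tail. This is why a published
overlap p of ~0.70 for a 37-vs-1,339 comparison (observed overlap 2)
cannot be checked against the one-to-one analytic value of ~0.62: it
depends on an unpublished duplication structure. The package demonstrates
this sensitivity with its synthetic spot map instead of targeting that
number.

`cross_species_overlap_p()` is the same machinery with an injective
ortholog map between two species' gene universes; unmapped genes can
never overlap.

## Co-expression procedure

The input is `log2(normalized count + 1)` for the `top_k = 8000` genes
with the highest variance of *normalized counts* (pre-log, matching the
convention of ranking on the normalized scale; a flag ranks post-log
instead). Steps:

1. Unsigned soft-threshold adjacency `|cor|^beta` with `beta = 20`
   (unsigned is the invoked framework's default; signed is available).
2. Topological overlap
   `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
   unit diagonal by convention, zero for isolated pairs.
3. Average-linkage hierarchical clustering on `1 - TOM`, with a *static*
   tree cut at height 0.99 (the original dynamic cut's parameters are not
   reproducible from a methods section; a fixed cut is transparent and
   deterministic), minimum module size 30, then iterative merging of
   modules whose eigengenes correlate above 0.75 (`merge_height = 0.25`).
   Unassigned genes form the `"grey"` non-module.
4. Colour labels assigned by decreasing module size along the conventional
   palette, so "turquoise" is always the largest module.
5. Module eigengenes: first principal component of the gene-standardized
   module expression, unit norm, sign-oriented to correlate positively
   with the module mean profile.
6. Eigengene–trait Pearson correlations with two-sided t-based p-values
   (n - 2 df), reporting both r and r² since conventions differ on which
   is printed.
7. Edge export of within-module pairs with TOM >= 0.2, deterministic
   ordering, suitable for network-visualization import.

`module_membership_test()` formalizes a "very high module membership"
claim: the statistic is the mean kME (gene-eigengene correlation) of a
gene set, and the null redraws same-size subsets of the same module;
p uses the plus-one convention. The choice of kME-mean against
within-module subsets is ours; the procedure it formalizes is not fully
specified in the methods literature it emulates.

Numerical notes: correlations are computed via a scaled cross-product
(BLAS) for speed; zero-variance genes get zeroed adjacency rows and a
warning; a degenerate all-equal TOM yields a single module or all-grey
with a report rather than an error.

## GO enrichment

`fisher_enrichment()` reports, per term, A (annotated in universe),
S (annotated in study set), E = A·|study|/|universe| (full precision
internally; round only for display) and the one-sided hypergeometric
upper-tail p. The weighted decorrelation algorithm of dedicated GO
packages is intentionally not re-implemented (it is intricate and
version-dependent); `mode = "elim"` offers the simpler
leaf-upward elimination: genes of a term significant at `elim_alpha` are
removed from its ancestors before those are tested, and a term with no
significant descendants keeps its classic p exactly. Enrichment p-values
computed against a specific annotation snapshot are therefore
approximated, not reproduced, by design.

## qPCR and display transforms

`delta_delta_ct()` implements 2^-ddCt with multiple reference genes
combined by the arithmetic mean of Ct (equivalent to a geometric mean of
linear quantities; the combination rule is unstated in common protocols,
and this is the stated choice), and a group-mean calibrator (per-sample
calibration is the other defensible reading; group mean is assumed and
documented). The companion `ddct_t_test()` works on log10 relative
expression. `zscore_by_gene()` centres and scales per gene over the four
genotype-by-condition group means by default — so "white = average
expression across groups" in a heatmap — with a per-sample mode available;
constant genes become zero rows and are flagged.

## Problem sizes and determinism

The default simulation is full study scale: ~24,000 genes by 16 samples,
with the network stage on the top 8,000 genes. On one CPU the full
pipeline (simulation, three callers, consensus, 8,000-gene TOM, modules,
eigengenes, edges) runs in a few minutes; the test suite uses this scale
for the end-to-end recovery checks and smaller scales elsewhere. Every
stochastic function takes an explicit seed and is bit-reproducible;
permutation results record `n_perm`, the seed and the p-value convention.

## Known limitations

* The three callers are simplified re-implementations; they are calibrated
  and validated on the generator, not intended to reproduce any specific
  package's numbers.
* The recovery properties quoted in the tests (consensus sensitivity,
  module ARI) are statements about the generator's noise model at its
  default settings.
* The elim mode is a decorrelation heuristic, not the weighted algorithm.
* The static tree cut can split or merge differently than a dynamic cut
  on shallow dendrograms; its parameters are exposed configuration.
* Overlap tests treat draws as uniform; no abundance- or length-biased
  sampling is modelled.
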