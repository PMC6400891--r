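# duomics

Integrative transcriptome–proteome analysis for factorial
(genotype × treatment) designs, built around the question: when a
mutation rewires gene expression, do the transcriptome and the proteome
move together? The package implements the full desk-side analysis stack
for a 2 × 2 seedling photobiology study design — two genotypes (wild type
vs. photoreceptor mutant), two light conditions (dark vs. red light),
four RNA-seq replicates and six 2D-gel replicates per group — together
with a synthetic-data generator that plants recoverable ground truth for
every stage, so the whole pipeline is testable with no external data.

## What it computes

**Consensus differential expression.** Counts are normalized with
median-of-ratios size factors; per-gene NB dispersions are
method-of-moments estimates shrunk toward an `a0 + a1/μ` trend. Three
simplified callers — an NB Wald test (quasi-likelihood-scaled, t
reference), an NB likelihood-ratio test (Bartlett-scaled), and a
pooled-variance t-test on `log2(normalized + 1)` — are BH-adjusted per
contrast, and a gene becomes a consensus DET only if called at q < 0.05
by ≥ 2 of 3 methods within every read-mapper group.

**2D-gel proteomics.** Spot volumes normalized against each gel's total
volume; per-spot Student's t-tests at raw p < 0.01 (deliberately no
multiple-testing correction, matching 2D-gel practice); spot sets
collapsed to gene sets through a many-to-one spot→gene map with
redundancy accounting.

**Overlap permutation tests.** The integration statistic: draw `n_a`
items from one universe (e.g. 218 protein spots) and `n_b` from another
(e.g. 23,876 genes), map the first draw to gene identifiers, count
distinct shared IDs, repeat 10,000 times, and report the upper-tail p for
the observed overlap. An exact hypergeometric oracle
(`analytic_overlap_p()`) covers the one-to-one case; a cross-species
variant draws through a reciprocal-best-hit ortholog map.

**Co-expression networks.** Top-8,000-variance genes,
unsigned soft-threshold adjacency `|cor|^β` with β = 20, topological
overlap (TOM), average-linkage clustering with a static cut, eigengene
merging, size-ranked colour labels, eigengene–trait correlations
(WT = 0 / mutant = 1, dark = 0 / red = 1), TOM ≥ 0.2 edge export, and a
permutation test for the module membership (mean kME) of a gene set.

**GO enrichment** (classic one-sided Fisher with A/S/E/p output and an
optional elim-style decorrelation) and **qPCR utilities**
(2^-ΔΔCt with dual reference genes; z-score matrices for heatmaps).

## Worked example

Simulate the default study, call consensus DETs for the dark-grown
genotype contrast, and test a DEP/DET overlap:

```r
library(duomics)

sim <- simulate_counts(study_design(), sim_config(n_genes = 4000, seed = 1))
sets <- dplyr::bind_rows(lapply(c("nb_wald", "nb_lrt", "logt"), \(cl)
  call_set(de_call(sim$counts, sim$design, c("WT_dark", "phyA_dark"), cl))))
consensus_calls(sets, min_methods = 2)
#> # A tibble: 967 × 4
#>    contrast             gene       support ok_default
#>    <chr>                <chr>        <int> <lgl>
#>  1 WT_dark_vs_phyA_dark gene_00015       3 TRUE
#>  2 WT_dark_vs_phyA_dark gene_00020       3 TRUE
#>  # …
```

967 genes pass the ≥2-of-3 consensus; `support` counts the agreeing
callers (minimum across mapper groups). Now the overlap of 39 significant
spots (drawn from 218) with 5,651 DETs (drawn from 23,876 genes), having
observed 23 shared gene IDs:

```r
res <- permutation_overlap_p(
  n_a = 39, n_b = 5651, observed = 23,
  universe_a = 218, universe_b = 23876, n_perm = 10000, seed = 1
)
res
#> Overlap permutation test (10000 permutations, seed 1, plus_one convention)
#>   observed overlap 23 | null mean 9.23 (var 7.24) | exceedances 0
#>   p = 9.999e-05
```

Random draws share ~9 genes on average; 23 was never reached in 10,000
permutations, so the overlap is far beyond chance
(p = 1/10001 under the never-zero plus-one convention; `convention =
"raw"` reports the exceedance proportion floored at 1/n_perm instead).
`tidy()`, `glance()` and `autoplot()` work on the result, as they do on
the co-expression network object from `coexpression_network()`.

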