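---
title: "Parsimonious gene correlation network analysis: models and methods"
author: "pgcna maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious gene correlation network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcna)
```

## The problem and the approach

Bulk expression time courses — for example arrays profiling the
maturation of antibody-secreting cells from proliferating plasmablast to
quiescent plasma cell under different survival conditions — contain
thousands of genes whose coordinated programs (unfolded-protein
response, cell-cycle exit, secretory optimization) unfold over days or
minutes. Classical weighted co-expression analysis keeps a dense,
soft-thresholded correlation matrix; `pgcna` instead takes the
*parsimonious* route: keep, for every gene, only its `k` strongest
positive Spearman correlations (default `k = 3`), symmetrize the result
into an undirected weighted graph, and find modules by maximizing
Newman–Girvan modularity with an ensemble of seeded Louvain runs. The
drastic sparsification (for a 9,063-gene course, from 41,064,453
evaluated pairs to a few tens of thousands of retained edges) makes
community detection fast and the resulting module structure stable and
interpretable.

The package covers the full workflow:

1. **Informative-probe selection** — per-contrast Welch t-tests
   (p and fold-change thresholds, both strict) unioned with a variance
   filter over per-(condition, timepoint) donor medians, then
   probe-to-gene merging.
2. **Network construction** — all-pairs Spearman, top-k retention,
   symmetrization (`m_ij = m_ji`).
3. **Module detection** — an ensemble of seeded Louvain runs, retaining
   the highest-modularity partitions and selecting a final clustering
   either by maximum Q or by signature-enrichment informativeness.
4. **Characterization** — hypergeometric signature enrichment,
   module/module and DE-set overlap significance, three-way Venn
   partitions, and module dynamics (donor medians, z-scores, fold
   changes vs. baseline, correlation-based row ordering).
5. **Validation** — a synthetic multi-donor time-course generator with
   planted modules, signatures and differential effects.

## Models and statistics

### Differential and variance selection

The per-probe test is a Welch two-sample t-test on log2 values with
Satterthwaite degrees of freedom — a deliberately assumption-light
choice; the test is configurable and only feeds a threshold rule. A
probe is called for a contrast (A, B) when its (optionally BH-adjusted)
p-value falls strictly below the threshold *and*
|mean(A) − mean(B)| strictly exceeds log2 of the fold-change threshold.
Selection mode uses unadjusted p < 0.01 (long course) or p < 0.05
(short course) with fold change > 1.2; differential sets for overlap
analyses use BH-adjusted p < 0.05 with fold change > 1.5. The variance
filter computes, per probe, the median across donors within each
(condition, timepoint) cell — a single-donor cell contributes its one
sample — and keeps probes whose unbiased variance across those medians
strictly exceeds 0.05. Grouping by condition × timepoint (rather than
pooling conditions per timepoint) preserves condition structure and is
the default; both groupings are available because either reading of
"per time point" is defensible for a multi-condition course.

When several selected probes map to one gene, the probe with the
largest variance across all samples represents the gene (ties broken by
lexicographically smaller probe id) — maximal-variance representatives
retain the most dynamic signal; the chosen probe is recorded as
provenance.

### The sparsified correlation graph

Spearman correlations use average ranks for ties; constant rows are
dropped with a warning before correlation since their rank correlation
is undefined. Partner ranking uses signed ρ and **only strictly
positive correlations are ever retained**: modularity on non-negative
weights is well defined, and a gene's "most correlated" partners are
most naturally its strongest positive ones. (Ranking by |ρ| is exposed
as an option, but negative edges never enter the graph.) Ties at the
k-th rank go to the lexicographically smaller partner id so the graph
is reproducible. A gene with no positive partner stays in the graph as
an isolated node and becomes a singleton module downstream. When every
node has at least k positive partners the retained undirected edge
count lies in [⌈kn/2⌉, kn]; the published long/short-course counts
(24,683 edges for n = 9,063; 11,458 for n = 4,705) sit inside this
bound at k = 3.

### Louvain ensemble and modularity

Modularity of a weighted partition is
Q = (1/2W) Σ_ij (w_ij − s_i s_j / 2W) δ(c_i, c_j). The Louvain
implementation is the classical two-phase greedy: local moving of nodes
to the neighboring community with the largest positive gain (ties to
the smallest community index), then aggregation of communities into
super-nodes, repeated until no move improves Q. The node visit order is
shuffled from an explicit integer seed, the only source of randomness;
a run is exactly reproducible from (graph, seed) and the caller's RNG
stream is never disturbed. The ensemble runs seeds
`baseSeed … baseSeed + nRuns − 1` (defaults: 10,000 runs, keep the 100
best by Q, ties by run index). The resolution parameter is fixed at 1 —
the original fast-unfolding formulation without resolution tuning.

Final-partition selection defaults to maximum modularity, which is
deterministic and reproducible. The alternative `"enrichment"` strategy
scores each retained partition by Σ over modules of −log10(best
signature FDR, floored at 1e−300) and picks the argmax — a quantitative
version of choosing the "most informative" clustering by signature
content; it can prefer a biologically resolved split over a coarser
merge that happens to score marginally higher Q. Module labels M1, M2,
… are assigned by non-increasing size with ties broken by smallest
member gene, so labelling never depends on run order.

### Enrichment, overlaps and multiplicity

All over-representation statistics reduce to one exact hypergeometric
upper tail: draw = the gene list, successes = the signature genes
intersected with the population, population = the annotated genes of
the platform (configurable to an explicit universe). Depletion uses the
lower tail. BH correction is applied jointly across the full module ×
signature family of one call — a single conservative, reproducible
correction family rather than per-module families. Display filtering
follows the module-heatmap rules: FDR < 0.1, signature size 5–1500
after intersection, top 30 per module. Module-to-module overlap between
two networks is tested at the gene level against the shared gene
universe and at the signature level on the sets of signatures passing
the prefilter (raw p < 0.001, size 5–1000), against the surviving
signature universe. Overlap significances are reported as −log10 p,
floored at 0 and capped at 300 for output stability.

### Dynamics

Module dynamics are computed on donor medians per
(condition, timepoint) cell. z-scores are taken per gene across those
group medians (not across raw samples), matching how module heatmaps
summarize a course; constant rows become all-zero and are flagged. Fold
changes are log2 differences against each condition's baseline column
(the earliest timepoint by default). Row ordering for heatmaps uses
agglomerative clustering with distance 1 − Pearson r and average
linkage; a constant row is assigned r = 0 (distance 1) to every other
row rather than an undefined correlation, and leaf-order ties follow
the input row order.

## The synthetic generator

`simulateTimecourse()` emulates the structure the pipeline is built
for: a condition × timepoint × donor design measured on a probe-level
array platform with multiple probes per gene. Defaults: 400 genes, 8
planted modules, 2 conditions × 8 timepoints × 3 donors, a 10%
fraction of null (moduleless) genes, probes per gene 1 + Poisson(0.3)
(mean 1.3), loadings uniform on 0.5–1.5, trajectory amplitude 2 log2
units, donor offsets sd 0.1, probe offsets sd 0.3, gene-level noise sd
0.5 and probe-level noise sd 0.25. Module trajectories are cubic
polynomials in normalized time with i.i.d. standard-normal
coefficients, drawn per condition, evaluated on the group grid,
orthogonalized across modules (QR) to remove accidental collinearity,
and rescaled to unit sd × amplitude. Because per-condition polynomials
differ, condition-differential effects arise naturally and the
noiseless gene × group surface is stored as ground truth: true
differential sets are read off it at a configurable threshold (default
log2 1.5), and `trueDifference()` gives the planted effect of any
contrast. One RNG stream is seeded once with a documented draw order,
so a config regenerates its dataset bit-for-bit. Planted signatures are
the exact module gene sets plus random decoys.

What the generator does *not* emulate: Illumina intensity
distributions, background/array batch effects, probe cross-
hybridization, or correlated noise between genes outside modules.
Passing recovery tests therefore demonstrates the pipeline's
correctness and power under idealized Gaussian noise, not its behavior
on raw array artifacts — normalization is explicitly upstream of this
package.

### Scoring recovery

Recovery is summarized by the adjusted Rand index between the recovered
partition and the planted one, computed over genes that carry a planted
module. Background genes are excluded from the score: they are mutually
uncorrelated by construction, so they have no true module to recover,
and counting "M0" as a class would penalize a method for refusing to
group unrelated genes (with the default 10% background even a perfect
recovery of all 8 modules would be capped near 0.85). The whole-universe
ARI is still reported by `moduleRecoveryARI()` as `ari_all` for
reference. At the default noise level the full pipeline (selection →
k = 3 network → 100-run ensemble → maximum-modularity selection)
recovers the planted modules essentially perfectly, and each recovered
module's top-ranked planted signature is its own.

## Numerical and engineering choices

- Strict inequalities everywhere a threshold is stated (p, fold change,
  variance, FDR), so boundary values are excluded reproducibly.
- A Welch test between two zero-variance groups with equal means
  returns t = 0, p = 1 rather than an error.
- Modularity of a zero-total-weight graph is an error; an edgeless
  graph still clusters (all singletons, Q = 0 by convention).
- Tie-breaks are always lexicographic or by index: k-th-rank partner,
  best-gain community, equal-variance probes, equal-Q ensemble runs,
  module relabelling.
- p-values are floored at 1e−300 before −log10; overlap significances
  are capped at 300.
- Every stochastic entry point (`louvainRun`, `clusterEnsemble`,
  `simulateTimecourse`, decoy drawing) takes an explicit seed, restores
  the caller's RNG state, and derives nothing from the ambient RNG.
- GEXF is written by hand (nodes with a string `module` attribute,
  edges with native `weight`) at full precision and read back with
  `xml2`; GraphML export delegates to igraph. Force-directed layout is
  out of scope — files are meant for Gephi-style viewers.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at desk scale, chosen as the
smallest sizes that still exercise every code path meaningfully:
ensembles of 100 runs on the 400-gene default dataset (5 replicate
seeds), exhaustive-enumeration cross-checks on graphs of 5–8 nodes
(Bell numbers up to 4,140 partitions), brute-force edge oracles up to
500 genes, and 10^5–10^6-draw Monte-Carlo checks of the hypergeometric
kernel. The published-scale run (9,063 genes, 10,000 Louvain runs)
uses identical code paths — only `nRuns` and the input size change.

## Known limitations

- The exact test behind the published probe counts is unspecified
  upstream; with the documented thresholds the selection reproduces the
  published counts approximately, not bit-exactly (the same holds for
  module counts, which depend on the legacy Louvain randomization).
- Only unpaired two-group contrasts are supported; no moderated
  (empirical-Bayes) tests, paired designs, or batch correction.
- Partial correlations, soft-threshold adjacency and Leiden refinement
  are out of scope by design.
- The enrichment universe defaults to the annotated platform genes;
  results are sensitive to that choice, which is why it is explicit.
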