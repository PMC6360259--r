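# pgcna — parsimonious gene correlation network analysis

`pgcna` maps modular gene expression in multi-donor, multi-condition
expression time courses — such as array profiles of antibody-secreting
cells maturing from plasmablast to plasma cell — by building deliberately
sparse co-expression networks and clustering them into modules. It is
aimed at transcriptomics and systems-biology analysts who want
interpretable expression modules, their signature biology, and their
dynamics over a time course, without the dense-matrix machinery of
soft-threshold co-expression methods.

## The method

1. **Informative-probe selection.** For each contrast of the design
   (conditions against each other per timepoint; timepoints against the
   course baseline), probes are called by Welch t-test with strict
   thresholds (selection mode: p < 0.01 long course / p < 0.05 short
   course, fold change > 1.2). The union with a variance filter
   (σ² > 0.05 across per-(condition, timepoint) donor medians) gives the
   non-redundant informative set; probes are then merged to genes,
   keeping the most variable probe per gene.
2. **Sparse network.** Spearman correlations ρ are computed for all
   n(n−1)/2 gene pairs; for each gene only its k = 3 most positively
   correlated partners are retained, and the matrix M is symmetrized by
   setting m_ij = m_ji. Edges with ρ ≤ 0 are never kept.
3. **Module detection.** The graph is clustered with an ensemble of
   seeded Louvain runs maximizing weighted Newman–Girvan modularity
   Q = (1/2W) Σ_ij (w_ij − s_i s_j/2W) δ(c_i, c_j); by default 10,000
   runs are performed, the 100 best by Q are retained, and the final
   partition is the maximum-Q one (or the most signature-informative
   one).
4. **Characterization.** Modules are tested against gene-signature
   collections (GMT) with the exact hypergeometric upper tail — draw =
   module genes, successes = signature genes, population = annotated
   platform genes — with BH FDR across the test family; module/module
   and DE-set overlaps use the same kernel and are reported as −log10 p.
   Module dynamics are donor-median profiles, per-gene z-scores and
   log2 fold changes against the course baseline.
5. **Validation.** A synthetic generator plants co-expression modules,
   signatures and differential effects in a donor × condition ×
   timepoint design so the whole pipeline can be exercised and scored
   (adjusted Rand index, signature recovery, DE sensitivity/FDR) with
   no external data.

## Worked example

```r
library(pgcna)

ds  <- simulateTimecourse(simConfig(seed = 1))   # 400 genes, 8 planted modules
ge  <- mergeProbesToGenes(syntheticExpr(ds),
                          rownames(syntheticExpr(ds)),
                          syntheticAnnotation(ds))
net <- buildNetwork(ge, k = 3)
net
#> CorrelationGraph: 400 genes, 1014 retained edges (k = 3 )
#>   pairs evaluated: 79,800

part <- selectPartition(clusterEnsemble(net, nRuns = 100, keep = 10,
                                        baseSeed = 42))
part
#> Partition: 400 genes in 8 module(s), Q = 0.865087
#>   sizes: M1=53 M2=52 M3=52 M4=51 M5=50 M6=49 M7=48 M8=45

head(enrichModules(part, plantedSignatureSet(ds), rownames(ge))[,
     c("module", "signature", "overlap", "module_size", "p", "fdr")], 4)
#>   module  signature overlap module_size            p          fdr
#> 1     M1 Planted_M4      45          53 1.121553e-51 3.140349e-50
#> 2     M2 Planted_M2      45          52 1.692910e-52 5.417314e-51
#> 3     M3 Planted_M8      45          52 1.692910e-52 5.417314e-51
#> 4     M4 Planted_M3      45          51 2.278918e-53 1.020955e-51

moduleRecoveryARI(part, ds)$ari
#> [1] 1
```

Reading the output: the top-3 retention kept 1,014 of 79,800 evaluated
pairs (~1.3%); the ensemble found 8 modules at modularity 0.865; every
recovered module's most significant signature is the gene set planted
for it (45 of its ~50 genes overlap; the remainder are background genes
absorbed into modules); the adjusted Rand index against the planted
partition is 1 — exact recovery.

The same workflow runs from files through one config:

```r
runPipeline(readPipelineConfig("pipeline.yaml"))
```

writing `genes.tsv`, `net.gexf`/`net.graphml` (for Gephi-style
viewers), `partition.tsv`, `ensemble.tsv`, `enrichment.tsv`, dynamics
profiles and a JSON manifest of seeds, thresholds and per-stage counts.
Example configurations for a long differentiation course and a short
stimulation course ship in `inst/extdata/`. A subcommand CLI wrapping
the same functions is installed at
`system.file("scripts", "pgcna", package = "pgcna")`.

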