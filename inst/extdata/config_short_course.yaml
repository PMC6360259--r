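# Short stimulation time course: probe selection at unadjusted
# p < 0.05, fold change > 1.2, variance filter sigma^2 > 0.05.
expr: expr.tsv
meta: meta.tsv
annot: annot.tsv
gmt: sigs.gmt
out_dir: results_stc
selection:
  p_threshold: 0.05
  fc_threshold: 1.2
  adjust: false
  variance_threshold: 0.05
network:
  k: 3
cluster:
  n_runs: 10000
  keep: 100
  base_seed: 42
  strategy: max_modularity
enrichment:
  min_size: 5
  max_size: 1500
  fdr_threshold: 0.1
  top: 30
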