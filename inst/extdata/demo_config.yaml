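# Demo run: small synthetic PitNET-style cohort through every stage.
seed: 7
out_dir: pitscape_demo
simulate:
  n_genes: 800
  n_cells: 1000
  clusters: {T01: 0.5, T02: 0.5}
  aggressive_fraction: 0.03
qc:
  mito_max: 0.5
  min_cells_per_gene: 3
markers:
  min_log_fc: 0.25
  max_adj_p: 0.01
classify:
  n_trees: 500
  min_log_fc: 0.75
  max_adj_p: 0.05
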