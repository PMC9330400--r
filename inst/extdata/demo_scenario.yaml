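tree:
  n_tips: 6
  depth: 300.0
rates:
  lambda: 0.002
  mu: 0.002
wgds:
- branch: N4
  position: 0.5
  retention_rate: 0.2
n_families: 200
filters:
  outgroup_min: 1
  other_min: 1
  max_per_taxon: 100
seq:
  syn_rate: 0.0025
  omega: 0.2
  n_codons: 200
go:
  n_categories: 10
  biased_categories: GO:0001
  enrichment_factor: 3.0
focal_species: t6
ks:
  window:
  - 0.01
  - 5.0
  k_max: 3
bd:
  subsets: 3
  subset_size: 60
  root_prior_mean: 1.0
design:
  n_trees_per_regime: 150
  positive_n_trees: 450
alpha: 0.05
seed: 42
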