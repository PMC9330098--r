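seed: 42
plif:
  sim_cutoff: 0.83
mining:
  min_coverage: 0.5
qsar:
  n_members: 20
  n_trees: 300
generator:
  n_active: 100
  n_inactive: 100
  library_size: 300
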