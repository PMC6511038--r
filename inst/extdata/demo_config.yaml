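# Desk-scale demo configuration: two small simulated studies on a
# 60-region atlas, 400 genes. Runs in a few seconds on one CPU.
seed: 42
simulate:
  n_regions: 60
  n_left: 30
  studies:
    - study_id: demoA
      n_cases: 25
      n_controls: 25
    - study_id: demoB
      n_cases: 25
      n_controls: 25
  n_affected: 6
  effect_size: 1.5
  expression:
    n_genes: 400
    n_signal_genes: 40
  network:
    n_nodes: 300
    clique_size: 20
  n_random_sets: 5
  random_set_size: 40
pls:
  n_perm: 199
  n_boot: 200
  n_perm_map: 199
case_control:
  n_perm_hub: 499
enrichment:
  n_resample: 499
  n_perm_edges: 499
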