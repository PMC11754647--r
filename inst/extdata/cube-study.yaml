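# Single-objective reference study: porosity minimisation in a 50 nm cube
# with 2HB edges, the M13mp18 scaffold budget and a 2.5 nm repulsion cutoff.
seed: 7
box: {a: 50, b: 50, c: 50, gamma: 90}
edge_type: {name: 2HB}
preserved:
  fixture: {name: cube_corners, side: 50}
constraints:
  scaffold_budget: 7249
  min_edge_nt: 31
  repulsion_cutoff_nm: 2.5
rules:
  k_min: 1
  k_max: 30
objectives:
  - {name: porosity, direction: minimize}
schedule:
  alpha: 0.95
  moves_per_stage: 50
  max_iter: 20000
  ramp_fraction: 0.3
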