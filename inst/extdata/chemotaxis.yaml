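# Linear MeAsp gradient in a closed 400 um channel, constant speed.
scenario: chemo
environment:
  x_min_um: 0
  x_max_um: 400
  ligand: {kind: linear, from: 0.0, to: 1.0}   # uM
abm:
  n_cells: 10000
  dt_s: 0.004
  t_end_s: 450
  t_burnin_s: 200
  seed: 1
  n_bins: 64
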