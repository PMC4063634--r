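# Linear pH gradient, wild-type Tar/Tsr mixture in the accuracy-optimal
# dissociation-constant regime.
scenario: ph
receptor:
  ph_regime: balanced
  f_a: 0.5
environment:
  x_min_um: 0
  x_max_um: 800
  ph: {kind: linear, from: 5.8, to: 8.2}
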