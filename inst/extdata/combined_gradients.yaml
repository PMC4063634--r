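# Opposing chemical and thermal gradients (Tar-only cells): temperature
# rises left to right, attractant falls; midpoint concentration 0.2 uM.
scenario: combined
environment:
  x_min_um: 0
  x_max_um: 500
  ligand: {kind: linear, from: 0.275, to: 0.125}   # 3 uM/cm opposing
  temperature: {kind: linear, from: 20, to: 30}
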