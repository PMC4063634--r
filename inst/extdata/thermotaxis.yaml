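# Linear temperature gradient spanning the critical temperature.
scenario: thermo
environment:
  x_min_um: 0
  x_max_um: 500
  temperature: {kind: linear, from: 20, to: 30}   # degC
speed:
  kind: constant
  v0_um_s: 20
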