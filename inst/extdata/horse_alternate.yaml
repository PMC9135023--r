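# Alternate horse preset with empirical forelimb length and GAD.
body:
  units: SI
  mass: 540
  g: 9.81
  l_H_max: 1.38
  l_F_max: 1.14
  gad: 1.63
  com_fraction: 0.57
  murphy: 0.82
  variant: distributed_mass
task:
  speed: 1.6
  stride: 1.856
objective: lew
transcription:
  n_nodes: 16
  collocation_rule: hermite_simpson
  relaxation_w0: 0.1
  c1: 0.00003
solver:
  n_restarts: 10
  base_seed: 1
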