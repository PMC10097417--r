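# Example run configuration: OSVZ division-rate replica at desk scale.
# Field names mirror the model parameter table; omitted fields keep
# their defaults.
preset: varying_g120_o20
seed: 1
mesh:
  n_radial: 20
  n_circumferential: 48
solver:
  dt: 0.5
  t_end: 60
  checkpoint_every: 10
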