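# Example dnarc run configuration (all omitted fields take defaults).
# A quick desk-scale arc on the built-in reference phantom.
phantom: reference
arc:
  start: 270          # lateral right ...
  stop: 130           # ... wrapping posteriorly: a 140 degree axial arc
  stages: 3           # evolutionary stages (2^s + 1 control points)
spot_pitch: 4         # mm, beam's-eye-view lattice
layer_spacing: 0.5    # cm WET between candidate energy layers
prescription: 50      # Gy, normalized at D95
norm_level: 95
collimation: none     # or per_beamlet_edge
objective: default    # or oar_avoidance
ga:
  population: 10
  generations: 15
  runts: 2
  weight_iters: 25
  polish_iters: 200
seed: 1
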