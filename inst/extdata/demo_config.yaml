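# Demo run: small phantom, reduced draw count, clinical-like noise.
phantom:
  shape: [24, 24, 12]
  lesion:
    center: [12, 12, 6]
    radius: 3
    ki: 0.05
    vp: 0.3
  aorta:
    center_xy: [5, 5]
    radius: 2
noise:
  alpha: 300
estimator:
  method: parapet
  n_draws: 200
  seed: 7
seed: 7
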