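# Example end-to-end configuration for the case-control longevity design.
design: longevity-case-control
models: [1, 2, 3, 4]
bootstrap_B: 1000
seed: 20170130
control_set: longevity-arm-controls
simulation:
  q_C: 0.291
  beta_GX: 0.301
  target_R2: 0.040
  tg_mean_TT: 1.29
  n_cases: 438
  n_controls: 2294
  n_ageing: 1750
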