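# Demo: fully synthetic four-patient cohort at reduced resolution.
# Calibrates each patient against a manufactured follow-up observation,
# predicts three years ahead, scores the cohort and compares the groups.
output_dir: plaquesim-demo-output
seed: 1
cohort:
  synthetic:
    n_patients: 4
    seed: 1
    grid_n: 60       # 60 x 60 cells of ~67 um over the 4 mm domain
solver:
  t_end: 36          # months
  snapshot_interval: 1
noise: 0
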