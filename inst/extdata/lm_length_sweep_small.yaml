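# Coupled logistic-map length sweep (C1 = 0, C2 = 0.1), reduced scale:
# 3 lengths x 25 realizations instead of the full 1000-realization sweep
# (scale factor 1/40); the AUC-vs-length shape is preserved, with wider
# per-level uncertainty.
name: lm_length_sweep_small
system: lm
method: both
design: length
levels: [100, 150, 400]
reps: 25
seed: 20230712
output_dir: lm_length_sweep_small_out
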