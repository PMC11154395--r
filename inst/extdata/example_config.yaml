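# Example configuration for run_analysis(): simulate a virtual study with
# the default design and reference parameters, then fit it.
simulate:
  noise_cv: 0.15
seed: 1
objective: least_squares
output_dir: tktd_out
lc50_duration: 96
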