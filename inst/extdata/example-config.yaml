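# Example run configuration for pegkin::pipeline_config(yaml = ...)
# Top-level keys override the package defaults; nested keys merge.
seed: 20230605
filter:
  low_cut: 1
  high_cut: 50
  order: 4
  zero_phase: true
apen:
  m: 2
  r: 0.2
accel:
  task: dominant
  n_pd: 20
  n_hc: 19
  duration: 4
  sampling_rate: 200
stats:
  covariates: true
  var_equal: false
  fdr_method: BH
  alpha: 0.05
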