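# Example pipeline configuration for run_pipeline().
# Stages run in order; each run is reproducible from this file + the seed.
stages:
  - synth
  - measure
  - correlate
  - split
  - timeseries
seed: 42
cohort:
  n: 100
  coupling_r: -0.6
  axis_length_range: [120, 2500]
  radius_range: [125, 250]
  noise_sd: 0.05
  outline_jitter: 0.02
timeseries:
  n_frames: 8
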