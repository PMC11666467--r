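# Example villimorph pipeline configuration (phantom mode).
# Run with: run_pipeline("example_pipeline.yaml") or
#   Rscript inst/cli/villimorph.R run --config example_pipeline.yaml --out out/
seed: 1
out_dir: villimorph_out
cohorts:
  - group: nulliparous
    n_mice: 3
    phantom:
      n_rows: 1
      n_cols: 2
      pitch_y: 30
      pitch_x: 30
      margin: 14
      shaft_length: 40
      radius: 8
      flattening: 1
      jitter: 1
      spacing: [1, 0.5, 0.5]
      clearance: 2
  - group: lactation
    n_mice: 3
    phantom:
      n_rows: 1
      n_cols: 2
      pitch_y: 40
      pitch_x: 42
      margin: 20
      shaft_length: 64
      radius: 8
      flattening: 2
      jitter: 1
      spacing: [1, 0.5, 0.5]
      clearance: 2
params:
  downsample_factors: [2, 4, 4]
  sigma_schedule: [8, 6]
  erosion_step: 2
  max_iterations: 8
  min_seed_volume: 100
surface_method: crofton
compare:
  metrics: [length, flatness]
  design: multi_group
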