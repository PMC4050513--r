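seed: 1
district: []
cohort:
  n_per_stratum: 250.0
fields:
  hcho:
    builder: formaldehyde_spec
  no2:
    builder: no2_spec
grid_resolution: 0.5
monitoring:
  k: 62.0
  inner_fraction: 0.5
  radius_km: 3.0
  missing_rate: 0.1
geostat:
  families:
  - exponential
  - spherical
  - gaussian
  theta_grid:
  - 90.0
  - 135.0
  ratio_grid:
  - 1.0
  - 0.7
  - 0.5
  n_bins: 12.0
outcomes: []
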