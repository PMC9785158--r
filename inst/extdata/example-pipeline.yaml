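seed: 7
output_dir: pipeline-out
geometry:
  fwhm: 4.0
  pattern_side: 4.0
  p0: 0.05
  p1: 0.90
  p2: 0.05
  proximity_radius: 2.0
  n_nuclei: 1000
data:
  simulate: true
  design:
    times: [0.5, 2.0, 4.0, 8.0, 24.0]
    n_dishes: 3
    n_nuclei: 1000
fit:
  parameterization: fraction
  beta0: free
  beta2: free
  n_starts: 16
robustness:
  enabled: false
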