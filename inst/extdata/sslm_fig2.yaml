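# Spatial and stochastic logistic model, reference parameterization.
# Desk-scale domain L = 200 (full-scale original: 800-by-800).
name: sslm_fig2
model:
  factory: sslm
  Aplus: 2.0
  Aminus: 1.0
  m: 1.0
  epsilon: 0.7071067811865476   # 1/sqrt(2): Gaussian shape exp(-|x|^2/2)
  truncation: 12.0
  shape: gaussian
domain:
  L: 200.0
  full_scale_L: 800.0
simulation:
  T: 30.0
  snapshot_spacing: 0.5
  seed: 1
  replicates: 3
  intensity: 1.0                # Poisson (complete spatial randomness)
analysis:
  window: [10.0, 30.0]          # skip the initial transient
  dt: [0.0, 0.5, 1.0]
  breaks: {from: 0.0, to: 8.0, by: 0.25}
  xi_n: 2048
  origin_stride: 0.5
  block_len: 5.0
thresholds:
  max_rms_frac: 0.10
  min_frac_z3: 0.80
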