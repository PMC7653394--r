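# Host-parasite model, reference parameterization.
# Desk-scale domain L = 200 (full-scale original: 800-by-800).
name: hp_fig3
model:
  factory: hp
  Aplus: 1.0
  Aminus: 0.1
  B: 1.0
  m: 1.0
  epsilon: 0.7071067811865476   # 1/sqrt(2): Gaussian shape exp(-|x|^2/2)
  truncation: 6.0
  shape: gaussian
domain:
  L: 200.0
  full_scale_L: 800.0
simulation:
  T: 70.0
  snapshot_spacing: 0.5
  seed: 1
  replicates: 1                 # single long run; window averaging
  intensity: [1.0, 0.3]         # hosts, parasites
analysis:
  window: [20.0, 70.0]
  dt: {from: 0.0, to: 10.0, by: 0.5}
  breaks: {from: 0.0, to: 2.0, by: 0.5}
  xi_n: 2048
  origin_stride: 0.5
  block_len: 5.0
thresholds:
  min_frac_z3: 0.80
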