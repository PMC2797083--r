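# Single source of truth for the built-in model presets.
# Units are the models' own dimensionless time/state units.
#
# fn: FitzHugh-Nagumo in FitzHugh's classical parameterization
#       dv = c (v + w - v^3/3) + I,   dw = -(v - a + b w) / c
#     a = 0.3, b = 0.8, c = 3 gives a stable limit cycle at zero input
#     (period ~= 10.4 time units, |v| <= ~2).
# hr: Hindmarsh-Rose
#       dx = y - a x^3 + b x^2 - z + I
#       dy = c - d x^2 - y
#       dz = r (s (x - x_r) - z)
#     with the standard seven constants.
#
# noise_mask / coupling_mask / input_mask: intrinsic noise, diffusive
# (gap-junction-like) coupling and the common input all act on the
# membrane-potential (first) component by default.
# ic_box: per-component box from which random initial conditions are drawn
# (covers the noise-free attractor with some margin).
fn:
  state_dim: 2
  params: {a: 0.3, b: 0.8, c: 3.0}
  noise_mask: [true, false]
  coupling_mask: [true, false]
  input_mask: [true, false]
  sigma_default: 0.5
  ic_box:
    - [-2.0, 2.0]
    - [-1.0, 1.5]
hr:
  state_dim: 3
  params: {a: 1.0, b: 3.0, c: 1.0, d: 5.0, r: 0.006, s: 4.0, x_r: -1.6}
  noise_mask: [true, false, false]
  coupling_mask: [true, false, false]
  input_mask: [true, false, false]
  sigma_default: 0.1
  ic_box:
    - [-1.5, 2.0]
    - [-10.0, 1.0]
    - [1.5, 3.5]
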