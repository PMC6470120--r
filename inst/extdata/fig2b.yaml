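# As fig1c, but with maximal spherical packaging-efficiency gains
# (alpha = 0, geometric exponent 1/3): g(k) = k^(1/3).
model:
  curve:
    form: diminishing
    rho: 0.1
    k_t: 5
    shape: 1.0
  efficiency:
    alpha: 0.0
    geom_exponent: 0.3333333333333333
sweep:
  axis1:
    name: curve.rho
    range: [0.001, 1.0]
    count: 25
    spacing: log
  axis2:
    name: curve.shape
    range: [0.1, 20.0]
    count: 25
    spacing: linear
output: results
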