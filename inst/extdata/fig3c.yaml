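# Optimal CIU size over defective proportion (mu) x diminishing-curve shape
# (a); low singleton success so group benefits favour CIUs at mu = 0.
model:
  curve:
    form: diminishing
    rho: 0.05
    k_t: 5
    shape: 1.0
sweep:
  axis1:
    name: mutation.mu
    range: [0.0, 0.95]
    count: 20
    spacing: linear
  axis2:
    name: curve.shape
    range: [0.1, 20.0]
    count: 10
    spacing: linear
output: results
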