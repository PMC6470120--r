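# Optimal CIU size over defective proportion (mu) x interfering fraction
# (iota), diminishing group benefits that favour CIUs at mu = 0, iota = 0.
model:
  curve:
    form: diminishing
    rho: 0.05
    k_t: 5
    shape: 5.0
sweep:
  axis1:
    name: mutation.mu
    range: [0.0, 0.95]
    count: 20
    spacing: linear
  axis2:
    name: mutation.iota
    values: [0.0, 0.0001, 0.001, 0.01, 0.1]
output: results
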