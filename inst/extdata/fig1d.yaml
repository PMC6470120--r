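# Optimal CIU size over singleton success (rho) x curve width,
# threshold (sigmoidal) group benefits, no efficiency gains, no mutation load.
model:
  curve:
    form: threshold
    rho: 0.1
    k_t: 5
    shape: 1.0
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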