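'n': 303
prevalence: 0.5445545
informative:
  oldpeak: 0.9
  thalach: 0.75
  age: 0.6
  chol: 0.45
  trestbps: 0.3
redundant_pairs:
- source: oldpeak
  copy: trestbps
  rho: 0.9
seed: 1
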