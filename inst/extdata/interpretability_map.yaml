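scores:
  age: 3.0
  sex: 3.0
  chol: 3.0
  trestbps: 3.0
  thal: 2.0
  ca: 2.0
  slope: 2.0
  restecg: 1.0
default_score: 2.0
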