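names:
- age
- sex
- cp
- trestbps
- chol
- fbs
- restecg
- thalach
- exang
- oldpeak
- slope
- ca
- thal
kinds:
- continuous
- binary
- categorical
- continuous
- continuous
- binary
- categorical
- continuous
- binary
- continuous
- categorical
- categorical
- categorical
levels:
  cp:
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  restecg:
  - 0.0
  - 1.0
  - 2.0
  slope:
  - 1.0
  - 2.0
  - 3.0
  ca:
  - 0.0
  - 1.0
  - 2.0
  - 3.0
  thal:
  - 3.0
  - 6.0
  - 7.0
label_name: target
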