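schema_version: 1
name: reference
n_compartments: 2
typical:
  CL: 0.3
  Vc: 3.5
  Q: 0.1
  Vp: 1.5
covariate_effects:
- target: CL
  covariate: wt
  form: power
  coefficient: 0.75
  reference: 70.0
- target: Vc
  covariate: wt
  form: power
  coefficient: 1.0
  reference: 70.0
- target: CL
  covariate: ada_positive
  form: binary_multiplier
  coefficient: 2.0
iiv_omega:
  parameters:
  - CL
  matrix:
    CL:
      CL: 0.09
iov_pi: 0.04
sigma_prop: 0.2
sigma_add: 0.0
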