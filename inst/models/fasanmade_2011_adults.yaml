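schema_version: 1
name: fasanmade_2011_adults
status: stub
source: Fasanmade et al. 2011 (CD, adults)
n_compartments: 2.0
typical:
  CL: ~
  Vc: ~
  Q: ~
  Vp: ~
covariate_effects:
- target: CL
  covariate: ada_positive
  form: binary_multiplier
  coefficient: ~
- target: CL
  covariate: alb
  form: power
  coefficient: ~
- target: CL
  covariate: imm
  form: binary_multiplier
  coefficient: ~
- target: CL
  covariate: wt
  form: power
  coefficient: ~
- target: Vc
  covariate: wt
  form: power
  coefficient: ~
iov_pi: transcribe
sigma_prop: ~
sigma_add: ~
notes: 'Structure-only stub: the functional skeleton of the published model. All parameter
  values (typical values, covariate coefficients, variances) must be transcribed from
  the original publication before this file can be loaded as an evaluable model. Weight
  also scales the peripheral volume.'
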