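schema_version: 1
name: buurman_2015
status: stub
source: Buurman et al. 2015 (CD/UC, adults)
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
  covariate: period
  form: binary_multiplier
  coefficient: ~
- target: CL
  covariate: sex
  form: binary_multiplier
  coefficient: ~
- target: Vc
  covariate: hbi
  form: proportional
  coefficient: ~
iov_pi: ~
sigma_prop: ~
sigma_add: ~
notes: 'Structure-only stub: the functional skeleton of the published model. All parameter
  values (typical values, covariate coefficients, variances) must be transcribed from
  the original publication before this file can be loaded as an evaluable model. ''period''
  distinguishes induction from maintenance phase.'
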