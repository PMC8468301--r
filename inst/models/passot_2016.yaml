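schema_version: 1
name: passot_2016
status: stub
source: Passot et al. 2016 (CD/UC)
n_compartments: 1.0
typical:
  CL: ~
  Vc: ~
covariate_effects:
- target: CL
  covariate: cd
  form: binary_multiplier
  coefficient: ~
- target: CL
  covariate: sex
  form: binary_multiplier
  coefficient: ~
- target: CL
  covariate: wt
  form: power
  coefficient: ~
- target: Vc
  covariate: cd
  form: binary_multiplier
  coefficient: ~
- target: Vc
  covariate: sex
  form: binary_multiplier
  coefficient: ~
- target: Vc
  covariate: wt
  form: power
  coefficient: ~
iov_pi: ~
sigma_prop: ~
sigma_add: ~
notes: 'Structure-only stub: the functional skeleton of the published model. All parameter
  values (typical values, covariate coefficients, variances) must be transcribed from
  the original publication before this file can be loaded as an evaluable model. '
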