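schema_version: 1
name: edlund_2017_1
status: stub
source: Edlund et al. 2017, variant I (CD, adults)
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
  covariate: wt
  form: power
  coefficient: ~
  reference: 70.0
- target: Vc
  covariate: wt
  form: power
  coefficient: ~
  reference: 70.0
iov_pi: ~
sigma_prop: ~
sigma_add: ~
notes: 'Structure-only stub: the functional skeleton of the published model. All parameter
  values (typical values, covariate coefficients, variances) must be transcribed from
  the original publication before this file can be loaded as an evaluable model. Variant
  I: ADA as a binary covariate on the patient level. Allometric weight scaling also
  on Q and Vp.'
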