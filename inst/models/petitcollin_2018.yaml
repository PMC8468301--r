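schema_version: 1
name: petitcollin_2018
status: stub
source: Petitcollin et al. 2018 (CD, children)
n_compartments: 1.0
typical:
  CL: ~
  Vc: ~
covariate_effects:
- target: CL
  covariate: alb
  form: power
  coefficient: ~
- target: CL
  covariate: time_varying_cl
  form: piecewise_time_multiplier
  coefficient: ~
iov_pi: ~
sigma_prop: ~
sigma_add: ~
notes: 'Structure-only stub: the functional skeleton of the published model. All parameter
  values (typical values, covariate coefficients, variances) must be transcribed from
  the original publication before this file can be loaded as an evaluable model. The
  published time-varying clearance / risk-of-immunization component is approximated
  by a piecewise time multiplier.'
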