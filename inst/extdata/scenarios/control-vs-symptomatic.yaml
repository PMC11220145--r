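# Two intermediate-allele groups generated from the SAME model (the null
# of no group difference, matching the negative published comparison).
# CAG weights decrease geometrically across the intermediate range, as in
# the population tail (27 CAGs > 28 CAGs > 29 CAGs ...), which places the
# cohort-average ratio near the published adjusted means.
type: group_comparison
name: control-vs-symptomatic
groups:
  control:
    n_samples: 46
  symptomatic:
    n_samples: 78
cag_range: [27, 35]
cag_weights: [1.0, 0.65, 0.4225, 0.274625, 0.17850625, 0.1160290625, 0.075418890625, 0.04902227890625, 0.0318644812890625]
age_range: [20.0, 90.0]
coefficients:
  intercept: -0.075
  beta_cag: 0.004
  beta_age: 0.0001
  beta_interaction: 0.0
noise_sd: 0.008
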