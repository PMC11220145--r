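# Intermediate-allele cohort at the published sample size, generated from
# the published per-category regression model. Intercept (not published)
# places the model mean mid-way through the published min-max ratio range;
# noise_sd is calibrated to that range (and agrees with the published R2).
type: cohort
name: IA-cohort-135
category: intermediate
n_samples: 135
cag_range: [27, 35]
age_range: [20.0, 90.0]
coefficients:
  intercept: -0.075
  beta_cag: 0.004
  beta_age: 0.0001
  beta_interaction: 0.0
noise_sd: 0.008
group: unknown
id_prefix: IA
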