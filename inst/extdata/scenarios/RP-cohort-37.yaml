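# Reduced-penetrance cohort at the published sample size; coefficients from
# the published regression, intercept placed mid-range, noise calibrated to
# the published min-max ratio span.
type: cohort
name: RP-cohort-37
category: reduced_penetrance
n_samples: 37
cag_range: [36, 39]
age_range: [20.0, 90.0]
coefficients:
  intercept: -1.457
  beta_cag: 0.047
  beta_age: 0.003
  beta_interaction: 0.0
noise_sd: 0.115
group: unknown
id_prefix: RP
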