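# Synthetic ten-brain-tissue panel of a heterozygous 17/33 CAG carrier.
# Somatic expansion is confined to the 33 CAG allele, with +1/+2 CAG
# template frequencies solved (tools/calibrate-scenarios.R) so the EXPECTED
# OBSERVED expansion ratio (somatic signal plus PCR stutter) equals
# target_ratio per tissue. Putamen and cerebellum targets are the
# published values (0.103, 0.048) and the +1/+2 observed frequencies are
# 2-fold and 5-fold higher in putamen than cerebellum; the eight other
# tissue totals are synthetic, interpolated with striatal regions
# highest.
type: tissue_panel
name: family-A-ten-tissues
alleles:
  short: {cag: 17, caacag: 1, ccgcca: 1, ccg: 7, cct: 2}
  long:  {cag: 33, caacag: 1, ccgcca: 1, ccg: 7, cct: 2}
depth: 20000
error_rate: 0.001
allele_balance: 0.5
window: 10
tissues:
  cerebellum:
    target_ratio: 0.048
    expansion_freqs: [0.0221397430916, 0.00150921109796]
  medulla:
    target_ratio: 0.055
    expansion_freqs: [0.0275862993026, 0.00252561722842]
  pons:
    target_ratio: 0.06
    expansion_freqs: [0.0314354947985, 0.00324354273113]
  occipital_lobe:
    target_ratio: 0.065
    expansion_freqs: [0.0352507973907, 0.00395490802821]
  temporal_lobe:
    target_ratio: 0.068
    expansion_freqs: [0.0375238778174, 0.00437863275645]
  frontal_lobe:
    target_ratio: 0.071
    expansion_freqs: [0.0397849899516, 0.00480006810173]
  hippocampus:
    target_ratio: 0.075
    expansion_freqs: [0.0427813415671, 0.00535846199941]
  substantia_nigra:
    target_ratio: 0.08
    expansion_freqs: [0.046497400547, 0.00605087248788]
  caudate_nucleus:
    target_ratio: 0.095
    expansion_freqs: [0.0574536070176, 0.00809181034454]
  putamen:
    target_ratio: 0.103
    expansion_freqs: [0.0631819240375, 0.00915865722443]
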