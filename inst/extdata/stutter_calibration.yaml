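# Default per-cycle slippage calibration for the branching PCR model.
# p_plus is solved (tools/calibrate-scenarios.R) so that the net-slippage
# distribution of a 33 CAG template after `cycles` cycles satisfies
# s(+1)/s(0) = target_plus1_ratio, the +1-product proportion of the
# pooled single-molecule assay. p_minus fixes the backward bias.
p_minus: 0.004
p_plus: 0.0015301849605
cycles: 30
length_scaling: 1.05
ref_cag: 33
target_plus1_ratio: 0.023
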