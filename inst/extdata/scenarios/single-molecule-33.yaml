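# Pooled single-molecule PCR stutter assay on a canonical 33 CAG template:
# 192 reactions (two 96-well plates), each seeded by one molecule, pooled
# into one library of 50,000 reads. Reproduces the +1-product proportion
# of ~2.3% that the stutter calibration targets.
type: single_molecule
name: single-molecule-33
template:
  cag: 33
n_reads: 50000
n_reactions: 192
error_rate: 0.001
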