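---
title: "Quantifying somatic CAG-repeat instability from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic CAG-repeat instability from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagmosaic)
```

## The measurement problem

The HTT exon-one CAG repeat expands somatically: over a carrier's lifetime,
a fraction of their cells gains repeat units beyond the inherited length,
and the rate of gain grows with both the inherited CAG count and age. Deep
amplicon sequencing of the repeat can measure this mosaicism directly, but
two obstacles stand between raw reads and a defensible per-sample estimate:

1. **PCR stutter.** The polymerase slips on the repeat during library
   amplification, producing products one or more units shorter (mostly) or
   longer (more rarely) than their template. Forward stutter is
   indistinguishable read-by-read from genuine somatic expansion.
2. **Allele interference.** In a heterozygote whose two alleles share the
   same interruption structure, backward stutter of the longer allele lands
   in the expansion window of the shorter one.

`cagmosaic` implements the full chain that deals with both: per-read
structure decomposition, stutter-aware genotyping, the expansion-ratio
statistic with an explicit single-molecule stutter baseline, allele
eligibility rules, and the cohort-level regression layer — plus a
synthetic-data module that generates every input the pipeline consumes, so
each stage is testable without access to patient data.

## Read decomposition and genotyping

Each read is anchored between fixed flank sequences (default: the 30 nt
5' and 21 nt 3' of the human HTT exon-one repeat region; up to 2
mismatches per anchor, indels not tolerated so anchoring stays
deterministic) and the inter-anchor segment is greedily decomposed as

```
(CAG)n (CAACAG)m (CCGCCA)k (CCG)p (CCT)q
```

A read passes only if the grammar consumes the whole segment. The `cag`
count is the *pure* uninterrupted tract — the CAA-CAG of the interruption
cassette is not included. This is the sequence-genotyper convention;
capillary sizing conventions can differ by the cassette length, which is
worth remembering when comparing numbers across platforms. Only the
forward read is used: a 400 nt forward read spans the repeat for every
allele the assay can size, and merging logic would add failure modes
without adding information.

The cassette composition defines a `variant_tag`: `canonical` (one CAACAG,
one CCGCCA), `loss_of_interruption` (both absent — an atypical structure
that segregates in some families and is associated with greater
instability), or `other`. Tags matter twice: expansions are only counted
within the inherited allele's tag, and a structure difference between
alleles restores eligibility of the short allele (below).

Genotyping reduces the (tag, CAG) histogram of passing reads to the two
inherited alleles. Candidate peaks are local maxima holding at least 1% of
passing reads (the noise floor); a peak within 2 CAG *below* a larger
same-tag peak is absorbed as backward stutter (backward slips dominate, and
the single-molecule experiment shows forward stutter is essentially
confined to +1, so forward products never form peaks of their own); a
sample is called homozygous when the top peak and its absorbed satellites
hold more than 85% of reads. More than two surviving peaks is an
ambiguous-genotype error rather than a guess. All thresholds live in
`htt_locus()` and a YAML locus file.

## The ratio of CAG expansions and its baseline

For an inherited allele with $n$ reads at the inherited length and
$n_{+i}$ reads $i$ repeats longer (same tag), the instability statistic is

$$\mathrm{ratio} = \frac{\sum_{i=1}^{10} n_{+i}}{n}.$$

The +10 window covers the somatic gains the assay actually observes (+1 to
+3); reads beyond the window stay in the profile's histogram but not in the
ratio.

The stutter baseline answers "what would this ratio be with *no* somatic
expansion?". Experimentally that is a single-molecule assay: dilute input
so each PCR sees one template molecule, pool many reactions, and sequence.
For a 33 CAG template the only larger products are +1, at about 2.3% of
the inherited-length products — so an observed ratio of 0.023 at 33 CAG is
explained by amplification alone, and `is_genuine_expansion()` applies a
strict point comparison against that baseline (the argument is "well
above", not a hypothesis test; an optional one-sided binomial test is
provided but off by default). Brain ratios of 0.048–0.103 clear it
comfortably.

Allele eligibility encodes the interference rule explicitly: the longer
allele is always usable; the shorter allele is usable iff its tag differs
from the longer allele's, or the CAG gap exceeds `window + guard`
(default 10 + 2, the absorption depth), so backward slippage from the long
allele cannot reach the short allele's window. One sample therefore
contributes at most two cohort records, usually one.

## The PCR stutter model

PCR is simulated as a conserved-template branching process: every cycle,
every molecule is copied once; the *copy* independently slips −1 repeat
with probability `p_minus`, +1 with `p_plus`, both scaled by
`length_scaling^(CAG − 33)`. Template strands persist unchanged, so a
random molecule in the final pool has experienced Binomial(cycles, 1/2)
synthesis events — with the consequence that for small rates the expected
+1 fraction is `cycles·p_plus/2`, *half* of what a model that re-replicates
every molecule each cycle would give. `slip_distribution()` computes the
exact net-offset distribution by dynamic programming, and the tests pin the
simulator to it and to the small-rate closed form.

Defaults (`inst/extdata/stutter_calibration.yaml`): 30 cycles,
`p_minus = 0.004`, `length_scaling = 1.05`, and `p_plus = 0.0015302`
solved so that s(+1)/s(0) = 0.023 at 33 CAG — the single observable the
stutter model is calibrated to. The backward rate and length scaling are
phenomenological choices (backward bias ≈ 2.6×; ~5% more slippage per
extra repeat), not fitted quantities: the assay protocol's cycle count and
polymerase are not in the text we model, so only the 2.3% observation
anchors the calibration.

Two simulation modes follow from one model:

* **Single-molecule mode** (`simulate_molecule_pcr()`) runs the branching
  process per reaction. A single reaction is *heavy-tailed*: a slip in
  cycle 1 puts ~25% of the pool at +1, so no handful of single reactions
  averages to 2.3%. The shipped `single-molecule-33` scenario pools 192
  reactions (two 96-well plates) into one 50,000-read library — which is
  what the dilution experiment does, and why it yields a stable proportion.
* **Bulk mode** (`simulate_tissue_reads()`) draws an independent net-slip
  offset per read from the exact marginal distribution. With nanogram
  input (thousands of template molecules) lineage correlations between
  reads are negligible, so the marginal is the right model and is far
  cheaper than per-molecule branching.

Somatic mosaicism enters at the template-pool stage: fraction
`expansion_freqs[i]` of the unstable allele's templates carry +i CAG
(multi-unit gains are template states, not slip events — the
single-molecule experiment saw no multi-unit slips). The implied true
ratio is $\sum f/(1-\sum f)$, and `expected_observed_ratio()` convolves
the pool with the slip distribution to give the expectation of what the
pipeline will measure: somatic signal, inflated by forward stutter,
slightly eroded by backward stutter of the expanded molecules.

## The shipped scenarios

The ten-tissue `family-A-ten-tissues` scenario emulates the brain of a
heterozygous 17/33 carrier (20,000 reads/tissue, 0.1% per-base error,
balanced alleles). Putamen (0.103) and cerebellum (0.048) totals and their
+1/+2 contrasts (2-fold and 5-fold) are the published values; per-tissue
template frequencies were solved at design time so the *expected observed*
full-window ratio equals each total exactly (each tissue's +1:+2 split is
rescaled by its own factor, so the cross-tissue folds hold to ~0.2%). The
eight unprinted tissue totals are synthetic, interpolated between the two
anchors with striatal regions highest, matching the known anatomical
gradient.

Cohort scenarios (`IA-cohort-135`, `RP-cohort-37`, `FP-cohort-88`)
generate ratio records from per-category planes

$$\mathrm{ratio} = \beta_0 + \beta_{CAG}\,\mathrm{CAG} + \beta_{age}\,\mathrm{age} + \varepsilon,$$

with CAG uniform on the category range, age uniform on 20–90 years, and
Gaussian noise truncated at zero. Slopes are the published estimates
(0.004/0.0001 for intermediate, 0.047/0.003 for reduced penetrance,
0.133/0.011 for the full ≥40 CAG analysis). Intercepts are not published;
each is placed so the model mean sits mid-way through the category's
published min–max ratio range (full penetrance: anchored near the
published minimum at the young/short corner instead, to keep
zero-truncation near 1%). Noise scales are calibrated to those ranges —
for the intermediate row the range- and R²-implied values coincide
(σ ≈ 0.008); for full penetrance the two conflict (the deterministic span
of the published slopes already exceeds the published range) and the
range-led value (0.15) wins. Truncation at zero is the one deliberate
departure from Gaussian residuals; it touches ~1% of full-penetrance
records and is recorded in each simulation's truth block.

`control-vs-symptomatic` draws both groups from the *same* intermediate
model (46 vs 78 records) — the generating truth is the null, matching the
negative published comparison — with geometrically decreasing CAG weights
(27 > 28 > 29 …, as in the population tail), which pulls the adjusted
means to ≈0.045, toward the published 0.035–0.038 rather than the ≈0.055 a
uniform CAG draw would give.

## The regression layer

`fit_category_regression()` is ordinary least squares of ratio on raw
(uncentred) CAG and age. Main effects, Wald 95% CIs, and two-sided p
values come from the main-effects model; the CAG×age interaction p from a
second, augmented fit — mirroring how a main-effects table with a single
interaction p is produced. α is 0.05 two-sided and no multiplicity
correction is applied anywhere, including the per-CAG age scan.
Category bounds are ≤26 / 27–35 / 36–39 / ≥40; a boundary allele of 27 is
intermediate by the definition of the intermediate range (tabulated bounds
that print "10–27" for normal are treated as a printing artefact). The
full-penetrance fit is configurable because two versions of that analysis
exist: `fp_mode = "table1"` restricts to 40–50 CAG, `"results_text"` uses
all ≥40 records.

The per-CAG age scan is offered in two stratifications — records at
exactly each length, and cumulatively at or above it — because a
"significant from CAG ≥ x" statement could arise from either; neither is
asserted as *the* published one. The adjusted group comparison is ANCOVA
(group + CAG + age), with adjusted means evaluated at the covariate grand
means.

## Numerical and degenerate-input choices

* Greedy decomposition is deterministic and backtick-free; a backtracking
  regular expression serves as the independent oracle in the tests, and
  the two agree on everything the simulator can emit.
* Local-maximum ties between adjacent histogram bins are both kept as
  candidates (at sequencing depth, exact ties are vanishingly rare).
* Rank-deficient designs (e.g. constant CAG within a stratum) raise an
  error naming the collinear term; strata with fewer than 3 records in the
  age scan are marked not-estimable rather than fitted.
* A ratio is undefined (error, not 0) when no reads sit at the inherited
  length; a fold change is undefined when the reference frequency is zero.
* Simulation is byte-deterministic given a seed: one seeded RNG stream per
  scenario run, seeds logged in output headers, FASTQ/TSV reruns hash
  identically.
* Counts exceeding integer range inside the branching process (beyond ~31
  cycles) fall back to a normal approximation of the binomial draw.

## What the tests do and do not show

The test-suite problem sizes are chosen to exercise every claim at
realistic scale on one CPU: 10,000-read oracle comparisons, 100-replicate
genotype recovery at 5,000 reads, 100-replicate slope recovery at the
published cohort sizes, 1,000-replicate CI-coverage calibration, 500-
replicate null-interaction uniformity (Kolmogorov–Smirnov at α = 0.01),
and a 5-seed run of the full ten-tissue fixture (the acceptance script
uses 50 seeds). Parameter-recovery is asserted two ways: each replicate's
95% CI covers the generating coefficient in ≥90/100 replicates, and the
across-replicate mean is within 15% of it. Point-wise containment of every
replicate inside the published CIs would be a different and unattainable
demand — the published age-slope CI's lower bound *equals* the rounded
point estimate, and the sampling dispersion of the slope at n = 135
exceeds that band for any unbiased estimator.

The generator emulates what the analysis assumes: per-base errors are
uniform (no quality-profile realism, no chimeras), stutter slips are
single-unit, mosaicism is at most +10, cohort residuals are Gaussian but
truncated. Passing tests therefore show the *pipeline* is correct and
well-calibrated under the stated model, not that the model captures every
artefact of real MiSeq libraries. Large rare expansions (the province of
small-pool PCR), contractions, capillary sizing and haplotype assignment
are out of scope by design.
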