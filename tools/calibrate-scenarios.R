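# Design-time calibration (run once from the repo root; outputs frozen
# into inst/extdata).
# 1. Solve p_plus so that the net-slippage distribution of a 33 CAG template
#    satisfies s(+1)/s(0) = 0.023 (the pooled single-molecule observation).
# 2. Solve the family-A per-tissue template expansion frequencies (f1, f2)
#    so that the EXPECTED OBSERVED per-offset ratios match the tissue
#    targets, which are fixed by four constraints: total observed ratios
#    0.103 (putamen) and 0.048 (cerebellum), and putamen/cerebellum fold
#    changes of 2 at +1 and 5 at +2.
library(cagmosaic)

p_minus <- 0.004; cycles <- 30L; scaling <- 1.05; ref <- 33L

plus1_ratio <- function(p_plus) {
  s <- slip_distribution(stutter_params(p_minus, p_plus, cycles, scaling, ref), 33)
  off <- as.integer(names(s))
  s[off == 1] / s[off == 0]
}
p_plus <- uniroot(function(x) plus1_ratio(x) - 0.023,
                  c(1e-4, 3e-3), tol = 1e-14)$root
cat(sprintf("p_plus = %.12g  (check s1/s0 = %.10f)\n", p_plus, plus1_ratio(p_plus)))

params <- stutter_params(p_minus, p_plus, cycles, scaling, ref)

# Per-offset observed targets. Solving r1_c + r2_c = 0.048,
# 2*r1_c + 5*r2_c = 0.103 gives the cerebellum split; putamen follows.
r1_c <- (5 * 0.048 - 0.103) / 3   # 0.0456667
r2_c <- 0.048 - r1_c              # 0.0023333
r1_p <- 2 * r1_c; r2_p <- 5 * r2_c
totals <- c(cerebellum = 0.048, medulla = 0.055, pons = 0.060,
            occipital_lobe = 0.065, temporal_lobe = 0.068,
            frontal_lobe = 0.071, hippocampus = 0.075,
            substantia_nigra = 0.080, caudate_nucleus = 0.095,
            putamen = 0.103)
tt <- (totals - 0.048) / (0.103 - 0.048)
targets <- cbind(r1 = r1_c + tt * (r1_p - r1_c), r2 = r2_c + tt * (r2_p - r2_c))
stopifnot(all(abs(rowSums(targets) - totals) < 1e-12))

solve_freqs <- function(r_target) {
  obs <- function(f) expected_observed_ratio(c(f[1], f[2]), params, 33)$per_offset[1:2]
  f <- pmax(r_target - c(0.023, 0), 1e-5)  # rough deconvolution start
  for (it in 1:20) {
    r <- obs(f)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      fj <- f; fj[j] <- fj[j] + 1e-7
      J[, j] <- (obs(fj) - r) / 1e-7
    }
    f <- f + solve(J, r_target - r)
  }
  stopifnot(max(abs(obs(f) - r_target)) < 1e-12, all(f > 0))
  f
}

# The published totals are FULL-WINDOW observed ratios; beyond-+2 stutter
# tails of the expanded templates add a little mass above the +1/+2
# offsets, so rescale the per-offset targets (preserving each tissue's
# +1:+2 split; the cross-tissue 2-fold/5-fold contrasts then hold to ~0.2%
# because each tissue rescales by its own factor) until the full-window
# expected ratio equals the total.
solve_freqs_total <- function(r_target, total) {
  f <- solve_freqs(r_target)
  for (it in 1:10) {
    full <- expected_observed_ratio(c(f[1], f[2]), params, 33)$ratio
    r_target <- r_target * total / full
    f <- solve_freqs(r_target)
  }
  stopifnot(abs(expected_observed_ratio(c(f[1], f[2]), params, 33)$ratio -
                  total) < 1e-10)
  f
}

freqs <- t(vapply(rownames(targets), function(tis)
  solve_freqs_total(targets[tis, ], totals[tis]), numeric(2)))
colnames(freqs) <- c("f1", "f2")
print(cbind(targets, freqs, total = rowSums(targets)))

# Emit the frozen YAMLs with full precision.
writeLines(c(
  "# Default per-cycle slippage calibration for the branching PCR model.",
  "# p_plus is solved (tools/calibrate-scenarios.R) so that the net-slippage",
  "# distribution of a 33 CAG template after `cycles` cycles satisfies",
  "# s(+1)/s(0) = target_plus1_ratio, the +1-product proportion of the",
  "# pooled single-molecule assay. p_minus fixes the backward bias.",
  sprintf("p_minus: %.12g", p_minus),
  sprintf("p_plus: %.12g", p_plus),
  sprintf("cycles: %d", cycles),
  sprintf("length_scaling: %.12g", scaling),
  sprintf("ref_cag: %d", ref),
  "target_plus1_ratio: 0.023"
), "inst/extdata/stutter_calibration.yaml")

tissue_block <- unlist(lapply(rownames(freqs), function(tis) c(
  sprintf("  %s:", tis),
  sprintf("    target_ratio: %.12g", totals[tis]),
  sprintf("    expansion_freqs: [%.12g, %.12g]", freqs[tis, 1], freqs[tis, 2])
)))
writeLines(c(
  "# Synthetic ten-brain-tissue panel of a heterozygous 17/33 CAG carrier.",
  "# Somatic expansion is confined to the 33 CAG allele, with +1/+2 CAG",
  "# template frequencies solved (tools/calibrate-scenarios.R) so the EXPECTED",
  "# OBSERVED expansion ratio (somatic signal plus PCR stutter) equals",
  "# target_ratio per tissue. Putamen and cerebellum targets are the",
  "# published values (0.103, 0.048) and the +1/+2 observed frequencies are",
  "# 2-fold and 5-fold higher in putamen than cerebellum; the eight other",
  "# tissue totals are synthetic, interpolated with striatal regions",
  "# highest.",
  "type: tissue_panel",
  "name: family-A-ten-tissues",
  "alleles:",
  "  short: {cag: 17, caacag: 1, ccgcca: 1, ccg: 7, cct: 2}",
  "  long:  {cag: 33, caacag: 1, ccgcca: 1, ccg: 7, cct: 2}",
  "depth: 20000",
  "error_rate: 0.001",
  "allele_balance: 0.5",
  "window: 10",
  "tissues:",
  tissue_block
), "inst/extdata/scenarios/family-A-ten-tissues.yaml")
cat("wrote calibration + family-A scenario\n")
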