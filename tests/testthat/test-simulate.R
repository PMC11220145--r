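test_that("the no-slip limit produces only the template length", {
  sm <- simulate_molecule_pcr(allele_structure(33),
                              stutter_params(p_minus = 0, p_plus = 0),
                              n_reads = 1000, seed = 701, error_rate = 0)
  expect_equal(sm$histogram$cag, 33L)
  expect_equal(sm$histogram$reads, 1000L)
  expect_identical(unique(sm$read_offsets), 0L)
})

test_that("small-rate +1 fraction matches the branching closed form", {
  # Under conserved-template branching, a random final molecule has
  # Binomial(cycles, 1/2) synthesis events, so for p_plus * cycles << 1 the
  # expected +1 fraction is cycles * p_plus / 2.
  p_plus <- 1e-4; cycles <- 30L
  closed_form <- cycles * p_plus / 2
  params <- stutter_params(p_minus = 0, p_plus = p_plus, cycles = cycles,
                           length_scaling = 1)
  sm <- simulate_molecule_pcr(allele_structure(33), params,
                              n_reads = 500000, n_reactions = 5000,
                              seed = 702, error_rate = 0)
  frac <- sum(sm$read_offsets == 1) / length(sm$read_offsets)
  mc_se <- sqrt(p_plus / 2 / sm$truth$n_reactions)  # early-slip dominated
  expect_lt(abs(frac - closed_form), max(0.1 * closed_form, 3 * mc_se))
  # the exact dynamic-programming distribution agrees too
  s <- slip_distribution(params, 33)
  expect_equal(unname(s["1"]), closed_form, tolerance = 0.01)
})

test_that("slip probabilities validate and scale with template length", {
  expect_error(stutter_params(p_minus = 0.6, p_plus = 0.5),
               class = "cagmosaic_error_invalid_params")
  expect_error(stutter_params(p_minus = -0.1),
               class = "cagmosaic_error_invalid_params")
  params <- stutter_params()
  expect_true(params$p_minus >= params$p_plus)  # backward bias
  s33 <- slip_distribution(params, 33)
  s43 <- slip_distribution(params, 43)
  expect_gt(s43["1"] / s43["0"], s33["1"] / s33["0"])
  expect_equal(sum(s33), 1, tolerance = 1e-12)
})

test_that("tissue simulation conserves reads and records a consistent truth", {
  sim <- simulate_tissue_reads(
    alleles = list(short = allele_structure(17), long = allele_structure(33)),
    mosaicism = mosaicism_model(c(0.05, 0.01)), depth = 2000, seed = 703
  )
  expect_length(sim$reads, 2000)
  expect_equal(sum(sim$truth$offsets$reads), 2000)
  expect_equal(sim$truth$n_long + sim$truth$n_short, 2000)
  expect_equal(sim$truth$true_ratio, 0.06 / 0.94, tolerance = 1e-12)
  expect_error(
    simulate_tissue_reads(alleles = allele_structure(33),
                          mosaicism = mosaicism_model(0.05), depth = 50),
    class = "cagmosaic_error_invalid_params")
  expect_error(mosaicism_model(c(0.8, 0.3)),
               class = "cagmosaic_error_invalid_params")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  run <- function(dir) {
    dir.create(dir, showWarnings = FALSE)
    simulate_tissue_reads(
      alleles = allele_structure(33), mosaicism = mosaicism_model(0.04),
      depth = 500, seed = 704, fastq = file.path(dir, "s.fastq"))
    sc <- simulate_scenario("IA-cohort-135", seed = 704, output_dir = dir)
    dir
  }
  d1 <- run(file.path(tempdir(), "det1"))
  d2 <- run(file.path(tempdir(), "det2"))
  for (f in c("s.fastq", "IA-cohort-135.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  d3 <- file.path(tempdir(), "det3")
  dir.create(d3, showWarnings = FALSE)
  simulate_tissue_reads(alleles = allele_structure(33),
                        mosaicism = mosaicism_model(0.04), depth = 500,
                        seed = 999, fastq = file.path(d3, "s.fastq"))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "s.fastq"))),
                         unname(tools::md5sum(file.path(d3, "s.fastq")))))
})

test_that("expected observed ratios encode the tissue contrasts by design", {
  fa <- load_scenario("family-A-ten-tissues")
  params <- stutter_params()
  per <- lapply(fa$tissues, function(cfg)
    expected_observed_ratio(unlist(cfg$expansion_freqs), params, 33))
  expect_equal(per$putamen$ratio, 0.103, tolerance = 1e-8)
  expect_equal(per$cerebellum$ratio, 0.048, tolerance = 1e-8)
  # folds are preserved to ~0.2%: each tissue's per-offset targets are
  # rescaled slightly (and independently) so its full-window total is exact
  expect_equal(per$putamen$per_offset[1] / per$cerebellum$per_offset[1], 2,
               tolerance = 0.01)
  expect_equal(per$putamen$per_offset[2] / per$cerebellum$per_offset[2], 5,
               tolerance = 0.01)
  expect_true(all(vapply(per, `[[`, 0, "ratio") > 0.023))
})

test_that("simulated tissue fold changes match the design within sampling error", {
  fa <- load_scenario("family-A-ten-tissues")
  alleles <- list(short = allele_structure(17), long = allele_structure(33))
  set.seed(705)
  put <- profile_from_sim(simulate_tissue_reads(
    alleles, mosaicism_model(unlist(fa$tissues$putamen$expansion_freqs)),
    depth = 20000, tissue = "putamen"))
  cer <- profile_from_sim(simulate_tissue_reads(
    alleles, mosaicism_model(unlist(fa$tissues$cerebellum$expansion_freqs)),
    depth = 20000, tissue = "cerebellum"))
  f1 <- tissue_fold_change(put, cer, 1)
  f2 <- tissue_fold_change(put, cer, 2)
  # 3-sigma bands from the per-offset binomial counts
  se_f1 <- 2 * sqrt(1 / put$n_plus[1] + 1 / cer$n_plus[1])
  se_f2 <- 5 * sqrt(1 / put$n_plus[2] + 1 / cer$n_plus[2])
  expect_lt(abs(f1 - 2), 3 * se_f1)
  expect_lt(abs(f2 - 5), 3 * se_f2)
})

test_that("cohort generation respects its contract", {
  expect_error(simulate_cohort(10, c(27, 35),
                               coeffs = list(intercept = 0, beta_cag = 0,
                                             beta_age = 0),
                               noise_sd = -1),
               class = "cagmosaic_error_invalid_params")
  sim <- simulate_cohort(500, c(36, 39),
                         coeffs = list(intercept = -1.457, beta_cag = 0.047,
                                       beta_age = 0.003),
                         noise_sd = 0.115, seed = 706)
  expect_true(all(sim$records$ratio >= 0))
  expect_true(all(sim$records$category == "reduced_penetrance"))
  expect_true(all(sim$records$inherited_cag %in% 36:39))
  expect_true(all(sim$records$age_at_sampling >= 20 &
                    sim$records$age_at_sampling <= 90))
})

test_that("nominal 95% CIs cover the generating age slope at the right rate", {
  m <- scenario_model("IA-cohort-135")
  set.seed(707)
  covered <- replicate(1000, {
    rec <- simulate_cohort(m$n_samples, m$cag_range, m$coeffs, m$noise_sd)$records
    ci <- fit_category_regression(rec)$ci95_age
    ci[1] <= m$coeffs$beta_age && m$coeffs$beta_age <= ci[2]
  })
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("the cohort chain recovers generating slopes for all four categories", {
  models <- c(lapply(c("IA-cohort-135", "RP-cohort-37", "FP-cohort-88"),
                     scenario_model),
              list(normal_cohort_model()))
  set.seed(708)
  for (m in models) {
    est <- replicate(300, {
      rec <- simulate_cohort(m$n_samples, m$cag_range, m$coeffs, m$noise_sd)$records
      fit <- fit_category_regression(rec)
      c(fit$beta_cag, fit$beta_age)
    })
    expect_lt(abs(mean(est[1, ]) - m$coeffs$beta_cag),
              0.1 * abs(m$coeffs$beta_cag))
    expect_lt(abs(mean(est[2, ]) - m$coeffs$beta_age),
              0.1 * abs(m$coeffs$beta_age))
  }
})

test_that("the read-level chain recovers the intermediate-allele slopes", {
  # simulate -> genotype -> ratio -> regress with PCR slippage disabled:
  # slippage adds a length-dependent stutter baseline to measured ratios
  # (absorbed into the coefficients of regressions on real measured data),
  # so the generating plane is recovered only for the somatic signal itself.
  m <- scenario_model("IA-cohort-135")
  quiet <- stutter_params(p_minus = 0, p_plus = 0)
  set.seed(709)
  cohort <- simulate_cohort(m$n_samples, m$cag_range, m$coeffs, m$noise_sd)$records
  measured <- vapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort$ratio[i]
    sim <- simulate_tissue_reads(
      alleles = allele_structure(cohort$inherited_cag[i]),
      mosaicism = mosaicism_model(r / (1 + r)), params = quiet,
      depth = 1500)
    profile_from_sim(sim)$ratio
  }, 0)
  chain <- cohort; chain$ratio <- measured
  fit <- fit_category_regression(chain)
  se_cag <- (fit$ci95_cag[2] - fit$ci95_cag[1]) / (2 * 1.96)
  se_age <- (fit$ci95_age[2] - fit$ci95_age[1]) / (2 * 1.96)
  expect_lt(abs(fit$beta_cag - m$coeffs$beta_cag), 3 * se_cag)
  expect_lt(abs(fit$beta_age - m$coeffs$beta_age), 3 * se_age)
})
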