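test_that("category boundaries follow the clinical definitions", {
  expect_equal(assign_category(c(10, 26, 27, 35, 36, 39, 40, 66)),
               c("normal", "normal", "intermediate", "intermediate",
                 "reduced_penetrance", "reduced_penetrance",
                 "full_penetrance", "full_penetrance"))
  expect_error(assign_category(0), class = "cagmosaic_error_invalid_cag")
})

test_that("noise-free records on a plane are recovered to numerical precision", {
  sim <- simulate_cohort(40, c(27, 35),
                         coeffs = list(intercept = 0.01, beta_cag = 0.004,
                                       beta_age = 0.0001),
                         noise_sd = 0, seed = 601)
  fit <- suppressWarnings(fit_category_regression(sim$records))  # perfect fit
  expect_equal(fit$beta_cag, 0.004, tolerance = 1e-10)
  expect_equal(fit$beta_age, 0.0001, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$ci95_cag[1] <= fit$beta_cag & fit$beta_cag <= fit$ci95_cag[2])

  # monotone growth: appending records exactly on the fitted plane leaves
  # the coefficients unchanged
  noisy <- simulate_cohort(60, c(27, 35),
                           coeffs = list(intercept = 0.01, beta_cag = 0.004,
                                         beta_age = 0.0001),
                           noise_sd = 0.01, seed = 602)$records
  fit1 <- fit_category_regression(noisy)
  b0 <- unname(coef(fit1$model)[1])
  extra <- data.frame(sample_id = paste0("X", 1:10),
                      inherited_cag = sample(27:35, 10, TRUE),
                      age_at_sampling = runif(10, 20, 90), group = "unknown")
  extra$ratio <- b0 + fit1$beta_cag * extra$inherited_cag +
    fit1$beta_age * extra$age_at_sampling
  extra$category <- assign_category(extra$inherited_cag)
  fit2 <- fit_category_regression(rbind(noisy, extra))
  expect_equal(fit2$beta_cag, fit1$beta_cag, tolerance = 1e-10)
  expect_equal(fit2$beta_age, fit1$beta_age, tolerance = 1e-10)
})

test_that("lm-based fits agree with an independent normal-equations solve", {
  set.seed(603)
  for (i in 1:20) {
    rec <- simulate_cohort(50, c(27, 35),
                           coeffs = list(intercept = runif(1, -0.1, 0.1),
                                         beta_cag = runif(1, 0, 0.01),
                                         beta_age = runif(1, 0, 3e-4)),
                           noise_sd = 0.01)$records
    fit <- fit_category_regression(rec)
    X <- cbind(1, rec$inherited_cag, rec$age_at_sampling)
    beta <- solve(t(X) %*% X, t(X) %*% rec$ratio)
    expect_equal(fit$beta_cag, beta[2], tolerance = 1e-8)
    expect_equal(fit$beta_age, beta[3], tolerance = 1e-8)
    expect_gte(fit$r2, 0); expect_lte(fit$r2, 1)
  }
})

test_that("coefficients are equivariant under scaling of the response", {
  rec <- simulate_cohort(80, c(27, 35),
                         coeffs = list(intercept = 0.02, beta_cag = 0.004,
                                       beta_age = 0.0001),
                         noise_sd = 0.008, seed = 604)$records
  fit <- fit_category_regression(rec)
  k <- 3.7
  rec2 <- rec; rec2$ratio <- rec2$ratio * k
  fit2 <- fit_category_regression(rec2)
  expect_equal(fit2$beta_cag, k * fit$beta_cag, tolerance = 1e-12)
  expect_equal(fit2$beta_age, k * fit$beta_age, tolerance = 1e-12)
  expect_equal(fit2$ci95_cag, k * fit$ci95_cag, tolerance = 1e-12)
  expect_equal(fit2$ci95_age, k * fit$ci95_age, tolerance = 1e-12)
  expect_equal(fit2$p_cag, fit$p_cag, tolerance = 1e-12)
  expect_equal(fit2$p_age, fit$p_age, tolerance = 1e-12)
  expect_equal(fit2$r2, fit$r2, tolerance = 1e-12)
})

test_that("degenerate designs raise informative errors", {
  rec <- simulate_cohort(30, c(33, 33),
                         coeffs = list(intercept = 0, beta_cag = 0.004,
                                       beta_age = 1e-4),
                         noise_sd = 0.005, seed = 605)$records
  expect_error(fit_category_regression(rec),
               regexp = "inherited_cag",
               class = "cagmosaic_error_rank_deficient")
  few <- simulate_cohort(5, c(27, 35),
                         coeffs = list(intercept = 0, beta_cag = 0.004,
                                       beta_age = 1e-4),
                         noise_sd = 0.005, seed = 606)$records
  expect_error(fit_category_regression(few),
               class = "cagmosaic_error_insufficient_records")
  bad <- few; bad$age_at_sampling <- NULL
  expect_error(fit_category_regression(bad), regexp = "age_at_sampling",
               class = "cagmosaic_error_schema")
})

test_that("interaction p-values are uniform under a null interaction", {
  m <- scenario_model("IA-cohort-135")
  set.seed(607)
  pvals <- replicate(500, {
    rec <- simulate_cohort(m$n_samples, m$cag_range, m$coeffs, m$noise_sd)$records
    fit_category_regression(rec)$interaction_p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the age-effect scan localises a known changepoint", {
  # age slope 0 below 29 CAG, strong positive slope at >= 29
  set.seed(608)
  rows <- lapply(27:35, function(L) {
    slope <- if (L >= 29) 0.001 else 0
    age <- runif(40, 20, 90)
    data.frame(sample_id = paste0("S", L, "_", 1:40), inherited_cag = L,
               age_at_sampling = age, group = "unknown",
               ratio = pmax(0.02 + slope * age + rnorm(40, 0, 0.008), 0))
  })
  rec <- do.call(rbind, rows)
  scan <- age_effect_scan(rec, 27, 35)
  expect_true(all(scan$estimable))
  expect_true(all(scan$p_age[scan$cag >= 29] < 0.05))
  expect_true(all(scan$p_age[scan$cag < 29] > 0.05))

  # a single record at a length is not estimable
  one <- rec[c(1, 41:80), ]
  scan1 <- age_effect_scan(one, 27, 28)
  expect_false(scan1$estimable[scan1$cag == 27])
  expect_true(is.na(scan1$beta_age[scan1$cag == 27]))

  # cumulative mode uses all records at or above each length
  cum <- age_effect_scan(rec, 27, 35, mode = "cumulative")
  expect_equal(cum$n, rev(cumsum(rev(tapply(rec$inherited_cag,
                                            rec$inherited_cag, length)))),
               ignore_attr = TRUE)
})

test_that("the per-length age scan has calibrated type-I error", {
  m <- scenario_model("IA-cohort-135")
  coeffs0 <- m$coeffs; coeffs0$beta_age <- 0
  set.seed(609)
  rejections <- unlist(lapply(1:100, function(i) {
    rec <- simulate_cohort(120, m$cag_range, coeffs0, m$noise_sd)$records
    scan <- age_effect_scan(rec, 27, 35)
    scan$p_age[scan$estimable] < 0.05
  }))
  rate <- mean(rejections)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("the adjusted group comparison is calibrated and recovers offsets", {
  m <- scenario_model("IA-cohort-135")
  gen_two_groups <- function(delta = 0) {
    a <- simulate_cohort(46, m$cag_range, m$coeffs, m$noise_sd,
                         group = "control", id_prefix = "C")$records
    b <- simulate_cohort(78, m$cag_range, m$coeffs, m$noise_sd,
                         group = "symptomatic", id_prefix = "P")$records
    b$ratio <- b$ratio + delta
    rbind(a, b)
  }
  set.seed(610)
  null_runs <- replicate(200, {
    cmp <- adjusted_group_comparison(gen_two_groups())
    c(cmp$p_group, cmp$difference)
  })
  expect_gt(stats::ks.test(null_runs[1, ], "punif")$p.value, 0.01)
  expect_lt(abs(mean(null_runs[2, ])),
            3 * sd(null_runs[2, ]) / sqrt(ncol(null_runs)))

  set.seed(611)
  deltas <- replicate(50, adjusted_group_comparison(
    gen_two_groups(delta = 0.01))$difference)
  expect_lt(abs(mean(deltas) - 0.01), 3 * sd(deltas) / sqrt(length(deltas)))

  too_few <- gen_two_groups()[c(1, 47:124), ]
  expect_error(adjusted_group_comparison(too_few),
               class = "cagmosaic_error_insufficient_records")
})

test_that("the shipped control-vs-symptomatic scenario yields the null result", {
  set.seed(612)
  nonsig <- replicate(20, {
    sim <- simulate_scenario("control-vs-symptomatic")
    adjusted_group_comparison(sim$records)$p_group >= 0.05
  })
  expect_gte(sum(nonsig), 16)  # ~95% expected under the generating null
  # adjusted means sit in the published neighbourhood (~0.035-0.038) by
  # construction of the CAG-weighted generator
  sim <- simulate_scenario("control-vs-symptomatic", seed = 613)
  cmp <- adjusted_group_comparison(sim$records)
  expect_true(all(cmp$adjusted_means > 0.02 & cmp$adjusted_means < 0.06))
})

test_that("cohort TSV round trip preserves records and validates schema", {
  sim <- simulate_cohort(20, c(27, 35),
                         coeffs = list(intercept = 0.01, beta_cag = 0.004,
                                       beta_age = 1e-4),
                         noise_sd = 0.005, seed = 614)
  path <- tempfile(fileext = ".tsv")
  write_cohort_tsv(sim$records, path, provenance = c(seed = "614"))
  back <- read_cohort_tsv(path)
  expect_equal(back$ratio, sim$records$ratio, tolerance = 1e-12)
  expect_equal(back$category, sim$records$category)
  expect_match(readLines(path, n = 1), "^# cagmosaic")
})
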