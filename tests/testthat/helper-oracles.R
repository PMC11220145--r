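# Independent oracles and shared fixtures for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Regex-based decomposition oracle: exact anchor location via fixed-string
# search, repeat grammar via a backtracking regular expression. Kept
# deliberately independent of the package's greedy scanning implementation.
oracle_decompose <- function(seq, locus = htt_locus()) {
  i5 <- regexpr(locus$anchor5, seq, fixed = TRUE)[1]
  if (i5 < 0) return(list(status = "no_anchor"))
  rest <- substr(seq, i5 + nchar(locus$anchor5), nchar(seq))
  i3 <- regexpr(locus$anchor3, rest, fixed = TRUE)[1]
  if (i3 < 0) return(list(status = "no_anchor"))
  seg <- substr(rest, 1, i3 - 1)
  m <- regmatches(seg, regexec(
    "^((?:CAG)+)((?:CAACAG)*)((?:CCGCCA)*)((?:CCG)*)((?:CCT)*)$", seg))[[1]]
  if (length(m) == 0) return(list(status = "ambiguous_decomposition"))
  counts <- nchar(m[-1]) / c(3, 6, 6, 3, 3)
  list(status = "pass", cag = counts[1], caacag = counts[2],
       ccgcca = counts[3], ccg = counts[4], cct = counts[5])
}

# Brute-force expansion-ratio oracle: expand the histogram into individual
# reads and count them one by one.
oracle_ratio <- function(hist, tag, cag, window = 10) {
  lens <- rep(hist$cag[hist$variant_tag == tag],
              hist$reads[hist$variant_tag == tag])
  sum(lens %in% (cag + 1):(cag + window)) / sum(lens == cag)
}

# Random repeat allele structure for property tests.
random_structure <- function() {
  caacag <- sample(0:2, 1)
  ccgcca <- if (caacag == 0) sample(c(0, 1), 1) else sample(0:1, 1)
  allele_structure(sample(5:60, 1), caacag, ccgcca,
                   ccg = sample(0:12, 1), cct = sample(0:3, 1))
}

# Synthetic read-call table (bypasses sequencing) for genotyper edge cases.
make_calls <- function(cags, reads_per, caacag = 1, ccgcca = 1) {
  cag <- rep(cags, reads_per)
  if (length(cag) == 0)
    return(data.frame(read_id = character(), status = character(),
                      cag = integer(), caacag = integer(), ccgcca = integer(),
                      ccg = integer(), cct = integer(),
                      variant_tag = character(), stringsAsFactors = FALSE))
  data.frame(
    read_id = paste0("r", seq_along(cag)), status = "pass", cag = cag,
    caacag = caacag, ccgcca = ccgcca, ccg = 7L, cct = 2L,
    variant_tag = if (caacag == 0 && ccgcca == 0) "loss_of_interruption"
                  else if (caacag == 1 && ccgcca == 1) "canonical" else "other",
    stringsAsFactors = FALSE
  )
}

# Expansion profile over a crafted histogram (canonical structure).
make_profile <- function(counts, inherited, window = 10) {
  h <- data.frame(variant_tag = "canonical",
                  cag = as.integer(names(counts)),
                  reads = as.numeric(counts))
  compute_expansion_ratio(h, allele_structure(inherited), window = window)
}

fixed_baseline <- function(cag, ratio) {
  structure(list(inherited_cag = as.integer(cag), baseline_ratio = ratio,
                 source = "single_molecule_experiment"),
            class = "baseline_model")
}

# Generating model of the normal-allele category (47 samples in the
# published cohort); not shipped as a scenario, shared across tests.
normal_cohort_model <- function() {
  list(n_samples = 47, cag_range = c(10, 26),
       coeffs = list(intercept = -0.0029, beta_cag = 0.001,
                     beta_age = -0.00002),
       noise_sd = 0.002)
}

# Scenario generating parameters as a plain list (n, range, coeffs, noise).
scenario_model <- function(name) {
  sc <- load_scenario(name)
  list(n_samples = sc$n_samples, cag_range = unlist(sc$cag_range),
       coeffs = sc$coefficients, noise_sd = sc$noise_sd)
}
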