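#' Ratio of CAG expansions for one allele
#'
#' Summarises somatic instability of one inherited allele as
#' `ratio = sum(n_plus[1:window]) / n`, where `n` is the number of reads at
#' the inherited length and `n_plus[i]` the number of reads `i` CAG longer,
#' counted only among reads sharing the allele's interruption structure
#' (`variant_tag`). Reads more than `window` repeats above the inherited
#' length are excluded from the ratio but retained in the profile's raw
#' histogram.
#'
#' @param histogram A (variant_tag, cag, reads) data.frame, or a
#'   `"sample_genotype"` whose histogram is used.
#' @param allele The inherited [allele_structure()] (or a list with
#'   `variant_tag` and `cag`).
#' @param window Count expansions up to this many CAG above the inherited
#'   length (default 10).
#' @param sample_id,tissue,allele_role Labels carried on the profile.
#'
#' @return An object of class `"expansion_profile"` with fields
#'   `inherited_cag`, `n`, `n_plus` (always the counts at +1..+10),
#'   `window`, `ratio`, the labels, and the same-structure raw histogram.
#' @examples
#' h <- data.frame(variant_tag = "canonical", cag = c(33, 34),
#'                 reads = c(1000, 23))
#' compute_expansion_ratio(h, allele_structure(33))$ratio  # 0.023
#' @export
compute_expansion_ratio <- function(histogram, allele, window = 10L,
                                    sample_id = NA_character_,
                                    tissue = NA_character_,
                                    allele_role = NA_character_) {
  if (inherits(histogram, "sample_genotype")) histogram <- histogram$histogram
  stopifnot(is.data.frame(histogram), window >= 1)
  window <- as.integer(window)
  tag <- allele$variant_tag
  cag <- as.integer(allele$cag)
  n <- hist_count(histogram, tag, cag)
  if (n == 0)
    cag_error("undefined_ratio",
              sprintf("no reads at the inherited length (%d CAG, %s)", cag, tag))
  n_plus <- vapply(1:10, function(i) hist_count(histogram, tag, cag + i), 0)
  ratio <- sum(n_plus[seq_len(min(window, 10L))]) / n
  structure(
    list(sample_id = sample_id, tissue = tissue, allele_role = allele_role,
         variant_tag = tag, inherited_cag = cag, n = n, n_plus = n_plus,
         window = window, ratio = ratio,
         histogram = histogram[histogram$variant_tag == tag, , drop = FALSE]),
    class = "expansion_profile"
  )
}

#' @export
print.expansion_profile <- function(x, ...) {
  cat(sprintf("<expansion_profile> %s%s: inherited %d CAG [%s], n=%d, ratio=%.4f (window +%d)\n",
              ifelse(is.na(x$sample_id), "", paste0(x$sample_id, " ")),
              ifelse(is.na(x$tissue), "", paste0("(", x$tissue, ")")),
              x$inherited_cag, x$variant_tag, x$n, x$ratio, x$window))
  invisible(x)
}

#' Allele eligibility for somatic expansion analysis
#'
#' When both alleles share the same interruption structure, backward PCR
#' slippage products of the longer allele can fall into the shorter
#' allele's expansion window and masquerade as somatic expansions of the
#' short allele. The longer allele is therefore always eligible, and the
#' shorter allele is eligible only when (a) its `variant_tag` differs from
#' the longer allele's (the two read populations are distinguishable by
#' structure), or (b) the CAG gap between the alleles exceeds
#' `window + guard`, so that backward slippage from the long allele cannot
#' reach the short allele's window.
#'
#' @param genotype A `"sample_genotype"`.
#' @param window Expansion-counting window (see [compute_expansion_ratio()]).
#' @param guard Extra CAG units of separation demanded beyond the window
#'   (default 2, the depth of backward stutter absorbed during genotyping).
#' @return A data.frame with one row per allele: `allele_role`, `cag`,
#'   `variant_tag`, `eligible`, `reason`.
#' @export
allele_eligibility <- function(genotype, window = 10L, guard = 2L) {
  stopifnot(inherits(genotype, "sample_genotype"), window >= 1, guard >= 0)
  short <- genotype$allele_short
  long <- genotype$allele_long
  gap <- long$cag - short$cag
  if (short$variant_tag != long$variant_tag) {
    short_ok <- TRUE
    reason <- sprintf("structure differs from longer allele (%s vs %s)",
                      short$variant_tag, long$variant_tag)
  } else if (gap > window + guard) {
    short_ok <- TRUE
    reason <- sprintf("CAG gap %d > window + guard (%d)", gap, window + guard)
  } else {
    short_ok <- FALSE
    reason <- sprintf(
      "same structure and CAG gap %d <= window + guard (%d): long-allele backward slippage can interfere",
      gap, window + guard)
  }
  data.frame(
    allele_role = c("short", "long"),
    cag = c(short$cag, long$cag),
    variant_tag = c(short$variant_tag, long$variant_tag),
    eligible = c(short_ok, TRUE),
    reason = c(reason, "longer allele is always eligible"),
    stringsAsFactors = FALSE
  )
}

#' Single-molecule PCR stutter baseline
#'
#' Expected ratio of CAG expansions produced by PCR slippage alone, i.e. in
#' the absence of somatic expansion, for a given inherited length. Derived
#' from the per-cycle branching slippage model ([slip_distribution()]):
#' `baseline = sum(s(+1..+window)) / s(0)`. With the shipped calibration
#' this is about 0.023 for a 33 CAG allele.
#'
#' @param inherited_cag Inherited pure-CAG length.
#' @param params Stutter parameters ([stutter_params()]).
#' @param window Expansion-counting window.
#' @param source Provenance label (`"simulator"` or
#'   `"single_molecule_experiment"`).
#' @return A list of class `"baseline_model"` with `inherited_cag`,
#'   `baseline_ratio` and `source`.
#' @export
stutter_baseline <- function(inherited_cag, params = stutter_params(),
                             window = 10L, source = "simulator") {
  s <- slip_distribution(params, inherited_cag)
  off <- as.integer(names(s))
  baseline <- sum(s[off >= 1 & off <= window]) / s[off == 0]
  structure(list(inherited_cag = as.integer(inherited_cag),
                 baseline_ratio = unname(baseline), source = source),
            class = "baseline_model")
}

#' Read / write a baseline model as JSON
#' @param path JSON file with fields `inherited_cag`, `baseline_ratio`,
#'   `source`.
#' @return A `"baseline_model"` list.
#' @export
read_baseline_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(is.numeric(b$baseline_ratio), b$baseline_ratio >= 0)
  structure(list(inherited_cag = as.integer(b$inherited_cag),
                 baseline_ratio = b$baseline_ratio,
                 source = b$source %||% "single_molecule_experiment"),
            class = "baseline_model")
}

#' @rdname read_baseline_json
#' @param baseline A `"baseline_model"`.
#' @export
write_baseline_json <- function(baseline, path) {
  jsonlite::write_json(unclass(baseline), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Is an observed expansion ratio genuine somatic expansion?
#'
#' Strict point comparison of the observed ratio against the PCR-stutter
#' baseline for the same inherited length: an observed ratio above the
#' baseline cannot be explained by amplification noise alone. An optional
#' one-sided binomial test (off by default) treats the expansion count as
#' binomial among (inherited + expanded) reads with success probability
#' `baseline / (1 + baseline)`.
#'
#' @param profile An `"expansion_profile"`.
#' @param baseline A `"baseline_model"` matched to the same inherited CAG.
#' @param test `"none"` (default) or `"binomial"`.
#' @return A list with `genuine` (logical), `margin`
#'   (`ratio - baseline_ratio`) and, for the binomial test, `p_value`.
#' @export
is_genuine_expansion <- function(profile, baseline, test = c("none", "binomial")) {
  test <- match.arg(test)
  stopifnot(inherits(profile, "expansion_profile"),
            inherits(baseline, "baseline_model"))
  if (profile$inherited_cag != baseline$inherited_cag)
    cag_error("baseline_mismatch",
              sprintf("profile inherited CAG (%d) does not match baseline (%d)",
                      profile$inherited_cag, baseline$inherited_cag))
  margin <- profile$ratio - baseline$baseline_ratio
  out <- list(genuine = profile$ratio > baseline$baseline_ratio,
              margin = margin)
  if (test == "binomial") {
    x <- sum(profile$n_plus[seq_len(profile$window)])
    out$p_value <- stats::binom.test(
      x, x + profile$n,
      p = baseline$baseline_ratio / (1 + baseline$baseline_ratio),
      alternative = "greater")$p.value
  }
  out
}

#' Per-offset fold change between two tissues
#'
#' Compares the frequency of `+i` CAG expansions (relative to inherited-
#' length reads) between two expansion profiles of the same inherited
#' allele: `fold = (n_plus_a[i]/n_a) / (n_plus_b[i]/n_b)`.
#'
#' @param profile_a,profile_b `"expansion_profile"` objects for the same
#'   inherited allele (e.g. putamen vs cerebellum).
#' @param i Expansion offset (1-10).
#' @return The fold change (a single number).
#' @export
tissue_fold_change <- function(profile_a, profile_b, i) {
  stopifnot(inherits(profile_a, "expansion_profile"),
            inherits(profile_b, "expansion_profile"),
            i >= 1, i <= 10)
  if (profile_a$inherited_cag != profile_b$inherited_cag ||
      profile_a$variant_tag != profile_b$variant_tag)
    cag_error("profile_mismatch",
              "profiles describe different inherited alleles")
  fa <- profile_a$n_plus[i] / profile_a$n
  fb <- profile_b$n_plus[i] / profile_b$n
  if (fb == 0)
    cag_error("undefined_fold",
              sprintf("zero +%d frequency in the reference profile", i))
  unname(fa / fb)
}

#' Flatten expansion profiles to a data.frame / TSV
#'
#' One row per profile: `sample_id`, `tissue`, `allele_role`,
#' `variant_tag`, `inherited_cag`, `n`, `n_plus_1` .. `n_plus_10`, `ratio`,
#' plus `eligible` and `genuine` flags when supplied.
#'
#' @param profiles A list of `"expansion_profile"` objects.
#' @param eligible,genuine Optional logical vectors aligned with `profiles`.
#' @return A data.frame.
#' @export
profiles_table <- function(profiles, eligible = NA, genuine = NA) {
  rows <- lapply(profiles, function(p) {
    np <- as.list(setNames(p$n_plus, paste0("n_plus_", 1:10)))
    c(list(sample_id = p$sample_id, tissue = p$tissue,
           allele_role = p$allele_role, variant_tag = p$variant_tag,
           inherited_cag = p$inherited_cag, n = p$n), np,
      list(ratio = p$ratio))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$eligible <- eligible
  out$genuine <- genuine
  out
}

#' @rdname profiles_table
#' @param path Output TSV path.
#' @param provenance Named character vector for the `#` header.
#' @export
write_profiles_tsv <- function(profiles, path, eligible = NA, genuine = NA,
                               provenance = NULL) {
  df <- if (is.data.frame(profiles)) profiles
        else profiles_table(profiles, eligible, genuine)
  write_tsv_with_header(df, path, provenance)
}
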