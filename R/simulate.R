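#' PCR stutter (slippage) parameters
#'
#' Per-cycle, per-copy-event slippage probabilities of the branching PCR
#' model: each time a molecule is copied, the nascent strand loses one
#' repeat unit with probability `p_minus`, gains one with probability
#' `p_plus`, and copies faithfully otherwise. Both probabilities are scaled
#' by `length_scaling^(cag - ref_cag)` for templates away from the
#' reference length. Contraction slips dominate (`p_minus >= p_plus` by
#' default). The default values are read from the packaged calibration
#' file, which fixes `p_plus` so that a single-molecule assay on a
#' `ref_cag` template yields a +1-product proportion of 2.3% after
#' `cycles` cycles.
#'
#' @param p_minus Per-cycle probability a nascent strand loses 1 CAG.
#' @param p_plus Per-cycle probability a nascent strand gains 1 CAG.
#' @param cycles Number of PCR cycles.
#' @param length_scaling Multiplier on both slippage probabilities per CAG
#'   above (or below) `ref_cag`.
#' @param ref_cag Reference CAG length of the calibration.
#' @return A list of class `"stutter_params"`.
#' @export
stutter_params <- function(p_minus = NULL, p_plus = NULL, cycles = NULL,
                           length_scaling = NULL, ref_cag = NULL) {
  cal <- stutter_calibration()
  p_minus <- p_minus %||% cal$p_minus
  p_plus <- p_plus %||% cal$p_plus
  cycles <- as.integer(cycles %||% cal$cycles)
  length_scaling <- length_scaling %||% cal$length_scaling
  ref_cag <- as.integer(ref_cag %||% cal$ref_cag)
  if (p_minus < 0 || p_plus < 0 || p_minus + p_plus >= 1)
    cag_error("invalid_params",
              "need 0 <= p_minus, p_plus and p_minus + p_plus < 1 per cycle")
  if (cycles < 1) cag_error("invalid_params", "cycles must be >= 1")
  if (length_scaling <= 0)
    cag_error("invalid_params", "length_scaling must be > 0")
  structure(list(p_minus = p_minus, p_plus = p_plus, cycles = cycles,
                 length_scaling = length_scaling, ref_cag = ref_cag),
            class = "stutter_params")
}

# Packaged calibration defaults (inst/extdata/stutter_calibration.yaml).
stutter_calibration <- function() {
  path <- system.file("extdata", "stutter_calibration.yaml",
                      package = "cagmosaic")
  yaml::read_yaml(path)
}

# Per-copy-event slip probabilities for a template of `cag` repeats.
slip_probs <- function(params, cag) {
  scale <- params$length_scaling^(max(cag, 1L) - params$ref_cag)
  pm <- params$p_minus * scale
  pp <- params$p_plus * scale
  if (pm + pp >= 1)
    cag_error("invalid_params",
              sprintf("scaled slippage probabilities sum to >= 1 at %d CAG", cag))
  list(pm = pm, pp = pp)
}

#' Net PCR slippage distribution of a random final molecule
#'
#' Under the branching model (template strands are conserved; each cycle
#' every molecule is copied once and only the copy may slip), a random
#' molecule in the final pool has experienced `Binomial(cycles, 1/2)`
#' synthesis events. This function returns the exact distribution of its
#' net repeat-unit offset by dynamic programming over cycles, using the
#' slippage probabilities of the template length (`length_scaling` along a
#' lineage is approximated by the template's own length).
#'
#' @param params [stutter_params()].
#' @param cag Template pure-CAG length.
#' @return A named numeric vector of probabilities; names are net offsets.
#' @export
slip_distribution <- function(params, cag) {
  pr <- slip_probs(params, cag)
  K <- params$cycles
  D <- numeric(2L * K + 1L)  # index i <-> offset i - K - 1
  D[K + 1L] <- 1
  stay <- 1 - pr$pm - pr$pp
  for (cyc in seq_len(params$cycles)) {
    slipped <- pr$pm * c(D[-1], 0) + stay * D + pr$pp * c(0, D[-length(D)])
    D <- 0.5 * D + 0.5 * slipped
  }
  setNames(D, seq_along(D) - K - 1L)
}

# Binomial draw tolerant of sizes beyond .Machine$integer.max (normal
# approximation is exact enough at that scale).
rbinom_big <- function(size, prob) {
  if (size <= 0 || prob <= 0) return(0)
  if (size <= .Machine$integer.max) return(rbinom(1L, size, prob))
  mu <- size * prob
  max(0, min(size, round(mu + sqrt(mu * (1 - prob)) * rnorm(1L))))
}

# One branching PCR reaction seeded by a single template molecule.
# Returns the final pool as counts named by net repeat offset.
pcr_branching_pool <- function(cag, params) {
  K <- params$cycles + 2L
  N <- numeric(2L * K + 1L)  # index i <-> offset i - K - 1
  N[K + 1L] <- 1
  for (cyc in seq_len(params$cycles)) {
    Nnew <- numeric(length(N))
    for (i in which(N > 0)) {
      copies <- N[i]
      pr <- slip_probs(params, cag + (i - K - 1L))
      down <- rbinom_big(copies, pr$pm)
      up <- rbinom_big(copies - down, pr$pp / (1 - pr$pm))
      Nnew[i - 1L] <- Nnew[i - 1L] + down
      Nnew[i + 1L] <- Nnew[i + 1L] + up
      Nnew[i] <- Nnew[i] + copies - down - up
    }
    N <- N + Nnew
  }
  names(N) <- seq_along(N) - K - 1L
  N[N > 0]
}

#' Simulate a pooled single-molecule PCR assay
#'
#' Models the stutter-baseline experiment: `n_reactions` independent PCRs,
#' each seeded by a single template molecule of the given structure, are
#' amplified for `params$cycles` cycles by a branching process in which
#' each copy event independently slips -1/+1 repeat with the per-cycle
#' probabilities. `n_reads` sequencing reads are then drawn from the pooled
#' final products (reactions contribute equally in expectation, as when
#' equal volumes are pooled into one library). A single reaction
#' (`n_reactions = 1`) has a heavy-tailed +1 proportion because an early
#' slip is inherited by a large fraction of the pool; the assay pools many
#' reactions precisely to average this out.
#'
#' @param template [allele_structure()] of the input molecule.
#' @param params [stutter_params()].
#' @param n_reads Total reads sampled across reactions.
#' @param n_reactions Number of pooled single-molecule reactions.
#' @param seed Optional RNG seed (`set.seed` is called when non-NULL).
#' @param error_rate Per-base sequencing error rate applied to emitted reads.
#' @param return_reads Also return the read sequences (default FALSE; the
#'   read-length histogram is always returned).
#' @param fastq Optional path; when given, reads are written as FASTQ
#'   (gzipped if the path ends in `.gz`) and `return_reads` is implied.
#' @param sample_id Label used in read ids and outputs.
#' @param locus Locus configuration used to render read sequences.
#'
#' @return A list with `histogram` (variant_tag, cag, reads of the sampled
#'   reads, before sequencing error), `read_offsets`, optionally `reads`
#'   and `read_ids`, and a `truth` record (seed, params, per-reaction read
#'   counts).
#' @export
simulate_molecule_pcr <- function(template, params = stutter_params(),
                                  n_reads, n_reactions = 1L, seed = NULL,
                                  error_rate = 0.001, return_reads = FALSE,
                                  fastq = NULL, sample_id = "single_molecule",
                                  locus = htt_locus()) {
  stopifnot(inherits(template, "allele_structure"), n_reads >= 1,
            n_reactions >= 1)
  if (!is.null(seed)) set.seed(seed)
  reads_per_reaction <- as.vector(rmultinom(1L, n_reads,
                                            rep(1, n_reactions)))
  offsets <- integer(0)
  for (r in seq_len(n_reactions)) {
    if (reads_per_reaction[r] == 0) next
    pool <- pcr_branching_pool(template$cag, params)
    drawn <- rmultinom(1L, reads_per_reaction[r], pool)[, 1]
    offsets <- c(offsets,
                 rep(as.integer(names(pool)), drawn))
  }
  tab <- table(offsets)
  hist <- data.frame(
    variant_tag = template$variant_tag,
    cag = template$cag + as.integer(names(tab)),
    reads = as.integer(tab),
    stringsAsFactors = FALSE
  )
  hist <- hist[order(hist$cag), , drop = FALSE]
  rownames(hist) <- NULL
  out <- list(histogram = hist, read_offsets = offsets,
              sample_id = sample_id,
              truth = list(seed = seed, params = params,
                           n_reactions = n_reactions,
                           reads_per_reaction = reads_per_reaction))
  if (return_reads || !is.null(fastq)) {
    seqs <- vapply(sort(unique(offsets)), function(k)
      render_allele_sequence(shift_allele(template, k), locus), "")
    names(seqs) <- sort(unique(offsets))
    reads <- unname(seqs[as.character(offsets)])
    reads <- apply_sequencing_errors(reads, error_rate)
    ids <- sprintf("sim:%s:%d", sample_id, seq_along(reads))
    out$reads <- reads
    out$read_ids <- ids
    if (!is.null(fastq)) write_fastq(reads, ids, fastq)
  }
  out
}

# Uniform per-base substitution errors.
apply_sequencing_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) ch[p] <- sample(bases[bases != ch[p]], 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Write reads as FASTQ
#'
#' Constant Q40 qualities; gzipped when the path ends in `.gz`.
#'
#' @param reads Character vector of read sequences.
#' @param ids Read identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, ids, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Somatic mosaicism model for one sample
#'
#' `expansion_freqs[i]` is the fraction of template DNA molecules of the
#' unstable allele that carry `inherited + i` CAG repeats (i = 1..10); the
#' remainder carry the inherited length. The implied true expansion ratio
#' in the template pool is `sum(f) / (1 - sum(f))`.
#'
#' @param expansion_freqs Numeric vector of template fractions; position i
#'   is the +i offset (length up to 10, padded with zeros).
#' @param target Which allele the mosaicism applies to (`"long"`, the
#'   unstable allele, or `"both"`).
#' @return A list of class `"mosaicism_model"`.
#' @export
mosaicism_model <- function(expansion_freqs, target = c("long", "both")) {
  target <- match.arg(target)
  f <- rep(0, 10)
  f[seq_along(expansion_freqs)] <- expansion_freqs
  if (any(f < 0) || sum(f) > 1)
    cag_error("invalid_params",
              "expansion_freqs must be >= 0 and sum to <= 1")
  structure(list(expansion_freqs = f, target = target,
                 true_ratio = sum(f) / (1 - sum(f))),
            class = "mosaicism_model")
}

#' Expected observed expansion ratio under mosaicism plus PCR stutter
#'
#' Convolves the template-pool composition of a [mosaicism_model()] with
#' the exact net-slippage distribution of the branching PCR model and
#' returns the expected read-level expansion ratio (what the sequencing
#' assay measures: genuine somatic expansion inflated by forward stutter
#' and slightly eroded by backward stutter of the expanded molecules).
#'
#' @param mosaicism A [mosaicism_model()] (or bare frequency vector).
#' @param params [stutter_params()].
#' @param cag Inherited pure-CAG length.
#' @param window Expansion-counting window.
#' @return A list with `per_offset` (expected `n_plus[i]/n` for i = 1..10)
#'   and `ratio` (their sum over the window).
#' @export
expected_observed_ratio <- function(mosaicism, params = stutter_params(),
                                    cag, window = 10L) {
  if (!inherits(mosaicism, "mosaicism_model"))
    mosaicism <- mosaicism_model(mosaicism)
  f <- mosaicism$expansion_freqs
  g <- c(1 - sum(f), f)  # template weights at offsets 0..10
  K <- params$cycles
  width <- 2L * (K + 12L) + 1L
  centre <- K + 13L
  cmix <- numeric(width)
  for (j in 0:10) {
    if (g[j + 1] == 0) next
    s <- slip_distribution(params, cag + j)
    off <- as.integer(names(s))
    cmix[centre + off + j] <- cmix[centre + off + j] + g[j + 1] * s
  }
  per_offset <- cmix[centre + 1:10] / cmix[centre]
  list(per_offset = per_offset,
       ratio = sum(per_offset[seq_len(min(window, 10L))]))
}

#' Simulate a bulk amplicon read set for one sample/tissue
#'
#' Draws each read's template from the mosaicism model (templates of the
#' unstable allele carry +i CAG with frequency `expansion_freqs[i]`),
#' applies bulk PCR stutter as an independent net-slippage offset per read
#' (the exact marginal of the branching model, appropriate for bulk input
#' DNA where reads descend from many independent template molecules), and
#' emits reads with uniform per-base sequencing error.
#'
#' @param alleles Either a single [allele_structure()] (single-allele
#'   sample) or a list with elements `short` and `long`.
#' @param mosaicism A [mosaicism_model()]; applied to the long allele (and
#'   the short one too when `target = "both"`).
#' @param params [stutter_params()].
#' @param depth Total reads (>= 100; smaller depths give unreliable ratios
#'   and are refused).
#' @param seed Optional RNG seed.
#' @param error_rate Per-base sequencing error rate.
#' @param allele_balance Expected fraction of reads drawn from the long
#'   allele (default 0.5).
#' @param sample_id,tissue Labels.
#' @param fastq Optional FASTQ output path.
#' @param locus Locus configuration used to render reads.
#'
#' @return A list of class `"tissue_sim"`: `reads`, `read_ids`,
#'   `sample_id`, `tissue`, `alleles`, and `truth` (template and slippage
#'   offset counts reconciling exactly with the emitted reads, the
#'   template-pool `true_ratio`, and the `expected_observed` ratio).
#' @export
simulate_tissue_reads <- function(alleles, mosaicism, params = stutter_params(),
                                  depth, seed = NULL, error_rate = 0.001,
                                  allele_balance = 0.5, sample_id = "sample",
                                  tissue = NA_character_, fastq = NULL,
                                  locus = htt_locus()) {
  if (depth < 100)
    cag_error("invalid_params",
              "depth < 100 refused: expansion ratios are unreliable")
  if (inherits(alleles, "allele_structure"))
    alleles <- list(short = alleles, long = alleles)
  stopifnot(inherits(mosaicism, "mosaicism_model"),
            inherits(alleles$short, "allele_structure"),
            inherits(alleles$long, "allele_structure"))
  if (!is.null(seed)) set.seed(seed)
  single <- identical(alleles$short, alleles$long)
  n_long <- if (single) as.integer(depth)
            else rbinom(1L, as.integer(depth), allele_balance)
  n_short <- as.integer(depth) - n_long
  f <- mosaicism$expansion_freqs
  draw_sample <- function(allele, n, mosaic) {
    if (n == 0L)
      return(data.frame(template_offset = integer(), net_slip = integer(),
                        reads = integer()))
    t_off <- if (mosaic) sample(0:10, n, replace = TRUE,
                                prob = c(1 - sum(f), f))
             else integer(n)
    out <- lapply(sort(unique(t_off)), function(j) {
      m <- sum(t_off == j)
      s <- slip_distribution(params, allele$cag + j)
      slip <- sample(as.integer(names(s)), m, replace = TRUE, prob = s)
      data.frame(template_offset = j, net_slip = slip)
    })
    out <- do.call(rbind, out)
    aggregate(list(reads = rep.int(1L, nrow(out))),
              by = out[c("template_offset", "net_slip")], FUN = sum)
  }
  mosaic_short <- mosaicism$target == "both" && !single
  long_tab <- draw_sample(alleles$long, n_long, TRUE)
  short_tab <- draw_sample(alleles$short, n_short, mosaic_short)
  render_reads <- function(allele, tab) {
    if (nrow(tab) == 0) return(character())
    total_off <- tab$template_offset + tab$net_slip
    seqs <- vapply(seq_len(nrow(tab)), function(i)
      render_allele_sequence(shift_allele(allele, total_off[i]), locus), "")
    rep(seqs, tab$reads)
  }
  reads <- c(render_reads(alleles$long, long_tab),
             render_reads(alleles$short, short_tab))
  perm <- sample.int(length(reads))
  reads <- apply_sequencing_errors(reads[perm], error_rate)
  ids <- sprintf("sim:%s:%d", sample_id, seq_along(reads))
  truth_tab <- rbind(
    if (nrow(long_tab)) cbind(allele_role = "long", long_tab),
    if (nrow(short_tab)) cbind(allele_role = "short", short_tab)
  )
  out <- structure(
    list(reads = reads, read_ids = ids, sample_id = sample_id,
         tissue = tissue, alleles = alleles,
         truth = list(seed = seed, offsets = truth_tab,
                      n_long = n_long, n_short = n_short,
                      true_ratio = mosaicism$true_ratio,
                      expected_observed = expected_observed_ratio(
                        mosaicism, params, alleles$long$cag)$ratio)),
    class = "tissue_sim"
  )
  if (!is.null(fastq)) write_fastq(reads, ids, fastq)
  out
}

#' Simulate a cohort of expansion-ratio records
#'
#' Draws inherited CAG uniformly (or with supplied weights) on a range, age
#' at sampling uniformly on `age_range`, and generates
#' `ratio = intercept + beta_cag * CAG + beta_age * age +
#' beta_interaction * CAG * age + Gaussian(0, noise_sd)`, truncated at 0
#' (ratios are nonnegative by construction; the truncation is a mild
#' departure from pure Gaussian residuals, recorded in the truth block).
#'
#' @param n_samples Number of records.
#' @param cag_range Length-2 integer range of inherited CAG.
#' @param coeffs List with `intercept`, `beta_cag`, `beta_age` and
#'   optionally `beta_interaction` (default 0).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param age_range Length-2 range of age at sampling (years).
#' @param group Group label stored on every record.
#' @param seed Optional RNG seed.
#' @param cag_weights Optional sampling weights across the CAG range
#'   (default uniform).
#' @param id_prefix Prefix for generated sample ids.
#'
#' @return A list with `records` (a cohort data.frame: `sample_id`,
#'   `inherited_cag`, `age_at_sampling`, `group`, `category`, `ratio`) and
#'   `truth` (generating coefficients, noise, seed, number of truncated
#'   records).
#' @export
simulate_cohort <- function(n_samples, cag_range, coeffs, noise_sd,
                            age_range = c(20, 90), group = "unknown",
                            seed = NULL, cag_weights = NULL,
                            id_prefix = "S") {
  if (noise_sd < 0) cag_error("invalid_params", "noise_sd must be >= 0")
  stopifnot(n_samples >= 1, length(cag_range) == 2,
            cag_range[2] >= cag_range[1], length(age_range) == 2,
            age_range[2] > age_range[1], is.finite(coeffs$intercept),
            is.finite(coeffs$beta_cag), is.finite(coeffs$beta_age))
  bint <- coeffs$beta_interaction %||% 0
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(cag_range[1], cag_range[2])
  cag <- grid[sample.int(length(grid), n_samples, replace = TRUE,
                         prob = cag_weights)]
  age <- runif(n_samples, age_range[1], age_range[2])
  raw <- coeffs$intercept + coeffs$beta_cag * cag + coeffs$beta_age * age +
    bint * cag * age + rnorm(n_samples, 0, noise_sd)
  records <- data.frame(
    sample_id = sprintf("%s%04d", id_prefix, seq_len(n_samples)),
    inherited_cag = cag,
    age_at_sampling = age,
    group = group,
    category = assign_category(cag),
    ratio = pmax(raw, 0),
    stringsAsFactors = FALSE
  )
  list(records = records,
       truth = list(coeffs = c(coeffs, list(beta_interaction = bint)),
                    noise_sd = noise_sd, seed = seed,
                    n_truncated = sum(raw < 0)))
}
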