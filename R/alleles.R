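#' Repeat allele structure
#'
#' Represents one HTT exon-one repeat allele as the length of its pure
#' (uninterrupted) CAG tract plus the composition of the downstream cassette
#' sequence: `(CAG)cag (CAACAG)caacag (CCGCCA)ccgcca (CCG)ccg (CCT)cct`.
#' The `cag` count deliberately excludes the CAA-CAG of the interruption
#' cassette, following the convention of sequence-based repeat genotypers;
#' capillary sizing conventions may differ by the cassette length.
#'
#' The `variant_tag` is derived from the cassette composition:
#' `"loss_of_interruption"` if and only if both the CAACAG and CCGCCA
#' cassettes are absent (the atypical structure lacking the entire
#' CAACAGCCGCCA intervening sequence between the CAG and CCG tracts, which
#' segregates with increased instability), `"canonical"` for the typical
#' single copy of each, `"other"` otherwise.
#'
#' @param cag Pure CAG repeat count (>= 1).
#' @param caacag Number of CAACAG cassettes (typically 0-2).
#' @param ccgcca Number of CCGCCA cassettes (typically 0-1).
#' @param ccg Number of CCG units.
#' @param cct Number of CCT units.
#'
#' @return An object of class `"allele_structure"`.
#' @examples
#' allele_structure(33)                      # canonical 33-CAG allele
#' allele_structure(32, caacag = 0, ccgcca = 0, ccg = 10)  # loss of interruption
#' @export
allele_structure <- function(cag, caacag = 1L, ccgcca = 1L, ccg = 7L, cct = 2L) {
  cag <- as.integer(cag)
  caacag <- as.integer(caacag)
  ccgcca <- as.integer(ccgcca)
  ccg <- as.integer(ccg)
  cct <- as.integer(cct)
  if (is.na(cag) || cag < 1L)
    cag_error("invalid_allele", "`cag` must be an integer >= 1")
  if (min(caacag, ccgcca, ccg, cct) < 0L)
    cag_error("invalid_allele", "cassette counts must be >= 0")
  structure(
    list(cag = cag, caacag = caacag, ccgcca = ccgcca, ccg = ccg, cct = cct,
         variant_tag = classify_variant(caacag, ccgcca)),
    class = "allele_structure"
  )
}

classify_variant <- function(caacag, ccgcca) {
  ifelse(caacag == 0L & ccgcca == 0L, "loss_of_interruption",
         ifelse(caacag == 1L & ccgcca == 1L, "canonical", "other"))
}

#' @export
print.allele_structure <- function(x, ...) {
  cat(sprintf("<allele_structure> %d CAG [%s] (CAG)%d(CAACAG)%d(CCGCCA)%d(CCG)%d(CCT)%d\n",
              x$cag, x$variant_tag, x$cag, x$caacag, x$ccgcca, x$ccg, x$cct))
  invisible(x)
}

#' @export
format.allele_structure <- function(x, ...) {
  sprintf("%d[%s]", x$cag, x$variant_tag)
}

#' Render an allele structure as an amplicon sequence
#'
#' Concatenates the 5' flank, the repeat-region motifs in grammar order, and
#' the 3' flank. Re-parsing the result with [anchor_and_decompose()] and
#' `max_mismatch = 0` recovers the identical structure.
#'
#' @param allele An [allele_structure()].
#' @param locus Locus configuration, see [htt_locus()].
#' @param flanks Include the anchor flanks (default `TRUE`).
#' @return A single DNA string.
#' @export
render_allele_sequence <- function(allele, locus = htt_locus(), flanks = TRUE) {
  stopifnot(inherits(allele, "allele_structure"))
  body <- paste0(
    strrep("CAG", allele$cag), strrep("CAACAG", allele$caacag),
    strrep("CCGCCA", allele$ccgcca), strrep("CCG", allele$ccg),
    strrep("CCT", allele$cct)
  )
  if (flanks) paste0(locus$anchor5, body, locus$anchor3) else body
}

# Same allele shifted by `offset` pure-CAG units (floored at 1); used by the
# simulators to render stutter/mosaicism products.
shift_allele <- function(allele, offset) {
  allele_structure(max(1L, allele$cag + as.integer(offset)), allele$caacag,
                   allele$ccgcca, allele$ccg, allele$cct)
}

#' Locus configuration for the HTT exon-one amplicon
#'
#' Bundles the anchor (flank) sequences that delimit the repeat region and
#' the read-level / genotype-level thresholds. The default anchors are the
#' 30 nt immediately 5' of the CAG tract and the 21 nt immediately 3' of the
#' CCT units of the human HTT exon one. All thresholds can be overridden
#' here or loaded from a YAML file with [locus_from_yaml()].
#'
#' @param anchor5,anchor3 Flank sequences delimiting the repeat region.
#' @param max_mismatch Maximum mismatches tolerated per anchor (no indels).
#' @param min_reads Minimum passing reads required to genotype a sample.
#' @param homozygosity_fraction A sample is called homozygous when the top
#'   peak (with its absorbed stutter satellites) holds more than this
#'   fraction of passing reads.
#' @param stutter_window Peaks within this many CAG below a larger
#'   same-structure peak are absorbed as backward PCR stutter.
#' @param peak_min_fraction Noise floor: a local maximum must hold at least
#'   this fraction of passing reads to be a candidate allele peak.
#' @param min_mean_quality Reads with mean base quality below this are
#'   flagged `low_quality` when read from FASTQ.
#' @return A list of class `"cag_locus"`.
#' @export
htt_locus <- function(anchor5 = "ATGAAGGCCTTCGAGTCCCTCAAGTCCTTC",
                      anchor3 = "CAGCTTCCTCAGCCGCCACCG",
                      max_mismatch = 2L,
                      min_reads = 100L,
                      homozygosity_fraction = 0.85,
                      stutter_window = 2L,
                      peak_min_fraction = 0.01,
                      min_mean_quality = 20) {
  stopifnot(nchar(anchor5) > 0, nchar(anchor3) > 0, max_mismatch >= 0,
            min_reads >= 1, homozygosity_fraction > 0.5,
            homozygosity_fraction <= 1, stutter_window >= 0,
            peak_min_fraction >= 0, peak_min_fraction < 1)
  structure(
    list(anchor5 = anchor5, anchor3 = anchor3,
         max_mismatch = as.integer(max_mismatch),
         min_reads = as.integer(min_reads),
         homozygosity_fraction = homozygosity_fraction,
         stutter_window = as.integer(stutter_window),
         peak_min_fraction = peak_min_fraction,
         min_mean_quality = min_mean_quality),
    class = "cag_locus"
  )
}

#' Load a locus configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [htt_locus()].
#' @return A `"cag_locus"` list.
#' @export
locus_from_yaml <- function(path) {
  if (!file.exists(path))
    cag_error("missing_file", sprintf("locus config not found: %s", path))
  do.call(htt_locus, yaml::read_yaml(path))
}
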