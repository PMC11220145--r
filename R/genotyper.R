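read_status_levels <- c("pass", "no_anchor", "ambiguous_decomposition",
                        "low_quality")

#' Anchor reads and decompose their repeat structure
#'
#' Each read is searched for the 5' and 3' anchor sequences (up to
#' `max_mismatch` mismatches each, indels not tolerated; the leftmost
#' acceptable occurrence is used for both, the 3' anchor being sought after
#' the 5'). The inter-anchor segment is then greedily decomposed
#' left-to-right into `(CAG)n (CAACAG)m (CCGCCA)k (CCG)p (CCT)q`. A read
#' passes only when the decomposition consumes the whole segment and at
#' least one CAG unit is present.
#'
#' @param reads Character vector of read sequences.
#' @param locus Locus configuration ([htt_locus()]).
#' @param max_mismatch Anchor mismatch tolerance; defaults to the locus value.
#' @param read_ids Optional read identifiers (default: names or index).
#'
#' @return A data.frame of read calls with columns `read_id`, `status`
#'   (`pass`, `no_anchor`, `ambiguous_decomposition`, `low_quality`), the
#'   motif counts `cag`, `caacag`, `ccgcca`, `ccg`, `cct` (NA unless
#'   `status == "pass"`), and `variant_tag`.
#' @examples
#' locus <- htt_locus()
#' read <- render_allele_sequence(allele_structure(33), locus)
#' anchor_and_decompose(read, locus)
#' @export
anchor_and_decompose <- function(reads, locus = htt_locus(),
                                 max_mismatch = locus$max_mismatch,
                                 read_ids = NULL) {
  if (length(reads) == 0)
    cag_error("empty_input", "no reads supplied")
  if (is.null(read_ids))
    read_ids <- names(reads) %||% paste0("read", seq_along(reads))
  # Decompose unique sequences once; deep amplicon read sets are highly
  # redundant so this is the main throughput lever.
  uniq <- unique(reads)
  idx <- match(reads, uniq)
  dec <- anchor_decompose_cpp(uniq, locus$anchor5, locus$anchor3,
                              as.integer(max_mismatch))
  out <- dec[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$status <- read_status_levels[out$status + 1L]
  out$variant_tag <- ifelse(out$status == "pass",
                            classify_variant(out$caacag, out$ccgcca),
                            NA_character_)
  cbind(data.frame(read_id = read_ids, stringsAsFactors = FALSE), out)
}

#' Read a FASTQ file into repeat-structure calls
#'
#' Single-end semantics: the (400 nt) forward read spans the whole repeat
#' for alleles in the sizable range, so only one mate is used. Reads whose
#' mean base quality falls below `locus$min_mean_quality` are flagged
#' `low_quality` and excluded from decomposition.
#'
#' @param path FASTQ file, optionally gzipped.
#' @inheritParams anchor_and_decompose
#' @return A read-call data.frame, as [anchor_and_decompose()].
#' @export
read_fastq_calls <- function(path, locus = htt_locus(),
                             max_mismatch = locus$max_mismatch) {
  if (!file.exists(path))
    cag_error("missing_file", sprintf("FASTQ not found: %s", path))
  fq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- as.character(fq)
  ids <- sub("\\s.*$", "", names(fq))
  mean_q <- vapply(as(Biostrings::quality(fq), "IntegerList"), mean, 0)
  calls <- anchor_and_decompose(seqs, locus, max_mismatch, read_ids = ids)
  low <- mean_q < locus$min_mean_quality
  if (any(low)) {
    calls$status[low] <- "low_quality"
    calls[low, c("cag", "caacag", "ccgcca", "ccg", "cct")] <- NA_integer_
    calls$variant_tag[low] <- NA_character_
  }
  calls
}

# (variant_tag, cag) read-count histogram over passing calls.
calls_histogram <- function(calls) {
  pass <- calls[calls$status == "pass", , drop = FALSE]
  if (nrow(pass) == 0)
    return(data.frame(variant_tag = character(), cag = integer(),
                      reads = integer(), stringsAsFactors = FALSE))
  agg <- aggregate(list(reads = rep.int(1L, nrow(pass))),
                   by = list(variant_tag = pass$variant_tag, cag = pass$cag),
                   FUN = sum)
  agg <- agg[order(agg$variant_tag, agg$cag), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

hist_count <- function(hist, tag, cag) {
  i <- which(hist$variant_tag == tag & hist$cag == cag)
  if (length(i) == 0) 0 else as.numeric(sum(hist$reads[i]))
}

# Stutter-aware peak calling on a (variant_tag, cag) histogram.
# Candidate peaks are local maxima above the noise floor; a candidate within
# `stutter_window` CAG below a larger surviving same-structure peak is
# absorbed as backward stutter. Returns surviving peaks with their mass
# (peak reads + absorbed satellite reads just below, same structure).
call_peaks <- function(hist, stutter_window = 2L, peak_min_fraction = 0.01) {
  total <- sum(hist$reads)
  cnt <- function(tag, cag) hist_count(hist, tag, cag)
  is_local_max <- mapply(function(tag, cag, reads) {
    reads >= cnt(tag, cag - 1L) && reads >= cnt(tag, cag + 1L)
  }, hist$variant_tag, hist$cag, hist$reads)
  cand <- hist[is_local_max & hist$reads >= peak_min_fraction * total, ,
               drop = FALSE]
  cand <- cand[order(-cand$reads, cand$cag), , drop = FALSE]
  surviving <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    absorbed <- any(
      surviving$variant_tag == cand$variant_tag[i] &
        cand$cag[i] >= surviving$cag - stutter_window &
        cand$cag[i] < surviving$cag &
        surviving$reads > cand$reads[i]
    )
    if (!absorbed) surviving <- rbind(surviving, cand[i, , drop = FALSE])
  }
  if (nrow(surviving) == 0)
    return(surviving)
  surviving$mass <- vapply(seq_len(nrow(surviving)), function(i) {
    sat <- seq_len(stutter_window)
    below <- vapply(sat, function(d) {
      pos <- surviving$cag[i] - d
      taken <- any(surviving$variant_tag == surviving$variant_tag[i] &
                     surviving$cag == pos)
      if (taken) 0 else cnt(surviving$variant_tag[i], pos)
    }, 0)
    surviving$reads[i] + sum(below)
  }, 0)
  surviving[order(-surviving$mass), , drop = FALSE]
}

#' Call a sample's inherited alleles from read calls
#'
#' Builds the (variant_tag, cag) histogram of passing reads and calls the
#' two inherited alleles by stutter-aware peak calling: candidate peaks are
#' local maxima of the histogram; a peak within `stutter_window` CAG below a
#' larger same-structure peak is absorbed as backward PCR stutter; the
#' sample is called homozygous when the top peak holds more than
#' `homozygosity_fraction` of the passing reads. More than two surviving
#' peaks raise an ambiguous-genotype error. Reads whose structure matches
#' neither inherited allele remain in the histogram but are never
#' attributed to an allele.
#'
#' @param calls Read-call data.frame from [anchor_and_decompose()] or
#'   [read_fastq_calls()].
#' @param locus Locus configuration supplying the default thresholds.
#' @param min_reads,homozygosity_fraction,stutter_window,peak_min_fraction
#'   Overrides for the locus thresholds (see [htt_locus()]).
#'
#' @return An object of class `"sample_genotype"`: fields `allele_short`,
#'   `allele_long` (both [allele_structure()]), `histogram`,
#'   `total_pass_reads`, `homozygous`, and the surviving `peaks`.
#' @export
genotype_sample <- function(calls, locus = htt_locus(),
                            min_reads = locus$min_reads,
                            homozygosity_fraction = locus$homozygosity_fraction,
                            stutter_window = locus$stutter_window,
                            peak_min_fraction = locus$peak_min_fraction) {
  hist <- calls_histogram(calls)
  total <- sum(hist$reads)
  if (total < min_reads)
    cag_error("insufficient_reads",
              sprintf("only %d passing reads; %d required", total, min_reads))
  peaks <- call_peaks(hist, stutter_window, peak_min_fraction)
  if (nrow(peaks) == 0)
    cag_error("ambiguous_genotype", "no allele peak found")
  if (nrow(peaks) > 2)
    cag_error("ambiguous_genotype",
              sprintf("%d allele peaks survive stutter absorption (max 2): %s",
                      nrow(peaks),
                      paste(sprintf("%d[%s]", peaks$cag, peaks$variant_tag),
                            collapse = ", ")))
  top_fraction <- peaks$mass[1] / total
  homozygous <- nrow(peaks) == 1 || top_fraction > homozygosity_fraction
  pick <- if (homozygous) peaks[c(1, 1), , drop = FALSE] else peaks
  pick <- pick[order(pick$cag), , drop = FALSE]
  alleles <- lapply(seq_len(2), function(i)
    modal_structure(calls, pick$variant_tag[i], pick$cag[i]))
  structure(
    list(allele_short = alleles[[1]], allele_long = alleles[[2]],
         histogram = hist, total_pass_reads = total,
         homozygous = homozygous, peaks = peaks),
    class = "sample_genotype"
  )
}

# Most frequent full cassette composition among passing reads at (tag, cag).
modal_structure <- function(calls, tag, cag) {
  at <- calls[calls$status == "pass" & calls$variant_tag == tag &
                calls$cag == cag, c("caacag", "ccgcca", "ccg", "cct"),
              drop = FALSE]
  key <- do.call(paste, c(at, sep = "/"))
  top <- strsplit(names(which.max(table(key))), "/", fixed = TRUE)[[1]]
  allele_structure(cag, top[1], top[2], top[3], top[4])
}

#' @export
print.sample_genotype <- function(x, ...) {
  cat(sprintf("<sample_genotype> %s / %s (%s), %d passing reads\n",
              format(x$allele_short), format(x$allele_long),
              if (x$homozygous) "homozygous" else "heterozygous",
              x$total_pass_reads))
  invisible(x)
}

#' Write a per-sample genotype histogram as TSV
#'
#' Columns `sample_id`, `variant_tag`, `cag`, `reads`, preceded by
#' `#`-prefixed provenance lines.
#'
#' @param genotype A `"sample_genotype"` (or bare histogram data.frame).
#' @param sample_id Sample identifier recorded in the first column.
#' @param path Output TSV path.
#' @param provenance Optional named character vector recorded in the header.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(genotype, sample_id, path, provenance = NULL) {
  hist <- if (inherits(genotype, "sample_genotype")) genotype$histogram
          else genotype
  out <- cbind(data.frame(sample_id = sample_id), hist)
  write_tsv_with_header(out, path, provenance)
}

write_tsv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cagmosaic %s", as.character(packageVersion("cagmosaic"))),
             con)
  for (nm in names(provenance))
    writeLines(sprintf("# %s=%s", nm, provenance[[nm]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
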