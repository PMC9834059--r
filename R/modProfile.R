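# Pileup-based RNA modification profiling.
#
# Modified bases that disrupt Watson-Crick pairing show up in cDNA
# sequencing as elevated reverse-transcription misincorporation (mismatch
# frequency) and as premature termination (drop-off) at the modified site.
# Profiles are compared between read populations defined by their 3' ends
# (e.g. precursor vs processed rRNA) to localize maturation-dependent
# modifications.

#' Build a per-site pileup from alignment records
#'
#' Counts, at every reference position, the aligned read bases (A/C/G/T and
#' "-" for deletions), matches and mismatches against the reference, and
#' drop-offs: the number of reads whose reverse-transcription 5'-most
#' aligned base is at the site (the end opposite the read's RNA 3' end).
#' Soft-clipped bases never enter the pileup. Deletions count as mismatches;
#' insertions are ignored.
#'
#' @param alignments alignment data.frame with aligned_seq covering
#'   [start, end) in reference-forward orientation.
#' @param reference contig sequence (character or \code{DNAString}).
#' @param contig contig name the pileup is built for (default: the single
#'   contig present in \code{alignments}).
#' @return data.frame, one row per covered-or-not position: contig, pos
#'   (0-based), ref_base, coverage, match, mismatch, n_A, n_C, n_G, n_T,
#'   n_del, dropoff, mismatch_frequency (NA where coverage is 0).
#' @export
buildPileup <- function(alignments, reference, contig = NULL) {
  if (!nrow(alignments))
    stop("invalid input: no alignments", if (!is.null(contig))
      paste0(" on contig ", contig))
  if (is.null(contig)) {
    contig <- unique(alignments$contig)
    if (length(contig) != 1L)
      stop("alignments cover several contigs; pass 'contig'")
  }
  aln <- alignments[alignments$contig == contig, , drop = FALSE]
  if (!nrow(aln)) stop("invalid input: no alignments on contig ", contig)
  refstr <- if (methods::is(reference, "DNAString") ||
                methods::is(reference, "DNAStringSet")) {
    if (methods::is(reference, "DNAStringSet")) {
      if (!contig %in% names(reference))
        stop("invalid input: contig ", contig, " absent from reference")
      as.character(reference[[contig]])
    } else as.character(reference)
  } else as.character(reference)
  L <- nchar(refstr)
  if (max(aln$end) > L)
    stop("invalid input: alignments extend past the reference end")
  ref_bases <- strsplit(refstr, "")[[1]]
  bases <- c("A", "C", "G", "T", "-")
  counts <- matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, bases))
  dropoff <- integer(L)
  for (i in seq_len(nrow(aln))) {
    s <- aln$start[i]; e <- aln$end[i]
    b <- strsplit(aln$aligned_seq[i], "")[[1]]
    if (length(b) != e - s)
      stop("aligned_seq length does not match the reference span for read ",
           aln$read_id[i])
    pos <- (s + 1L):e
    for (base in bases) {
      sel <- b == base
      if (any(sel)) counts[pos[sel], base] <- counts[pos[sel], base] + 1L
    }
    # drop-off: last position in reverse-transcription direction
    drop_pos <- if (aln$strand[i] == "-") s + 1L else e
    dropoff[drop_pos] <- dropoff[drop_pos] + 1L
  }
  coverage <- as.integer(rowSums(counts))
  match_idx <- cbind(seq_len(L), match(ref_bases, bases))
  match_n <- ifelse(is.na(match_idx[, 2]), 0L, counts[match_idx])
  mism <- coverage - match_n
  data.frame(contig = contig, pos = 0:(L - 1L), ref_base = ref_bases,
             coverage = coverage, match = as.integer(match_n),
             mismatch = as.integer(mism),
             n_A = counts[, "A"], n_C = counts[, "C"], n_G = counts[, "G"],
             n_T = counts[, "T"], n_del = counts[, "-"],
             dropoff = dropoff,
             mismatch_frequency = ifelse(coverage > 0, mism / coverage,
                                         NA_real_),
             stringsAsFactors = FALSE)
}

#' Flag candidate modified sites in a pileup
#'
#' Sites with mismatch frequency at or above \code{mask_threshold} are
#' flagged; sites below it (or without coverage) are masked. The local
#' drop-off rate (drop-offs over coverage) is co-reported, as modified
#' sites often show coverage decay in addition to miscalls.
#'
#' @param profile data.frame from \code{\link{buildPileup}}.
#' @param mask_threshold minimal mismatch frequency retained (default 0.1).
#' @return \code{profile} with added columns flagged (logical),
#'   mask_reason (NA, "below_threshold" or "no_coverage") and dropoff_rate.
#' @export
flagModifiedSites <- function(profile, mask_threshold = 0.1) {
  f <- profile$mismatch_frequency
  flagged <- !is.na(f) & f >= mask_threshold
  profile$flagged <- flagged
  profile$mask_reason <- ifelse(flagged, NA_character_,
                                ifelse(profile$coverage == 0, "no_coverage",
                                       "below_threshold"))
  profile$dropoff_rate <- ifelse(profile$coverage > 0,
                                 profile$dropoff / profile$coverage, NA_real_)
  profile
}

#' Contrast per-site mismatch profiles of two read populations
#'
#' Builds pileups for both populations over the same reference and reports
#' the per-site mismatch-frequency delta (A minus B). Sites where both
#' frequencies are below \code{mask_threshold} are masked; the outlier
#' ranking orders unmasked sites by |delta|, so a maturation-specific
#' modification surfaces as the top-ranked site.
#'
#' @param popA,popB alignment data.frames (e.g. the two 3'-end-defined
#'   isoform populations produced with \code{\link{assignReads}}).
#' @param reference contig sequence.
#' @param contig contig name (default taken from popA).
#' @param mask_threshold masking threshold on both frequencies (default
#'   0.1).
#' @param min_coverage sites covered by fewer reads than this in either
#'   population are masked: a frequency from a handful of reads is too
#'   noisy to rank (default 20).
#' @return data.frame: pos, freq_A, freq_B, delta, masked, rank (by |delta|
#'   among unmasked sites, NA for masked).
#' @export
compareProfiles <- function(popA, popB, reference, contig = NULL,
                            mask_threshold = 0.1, min_coverage = 20L) {
  if (!nrow(popA) || !nrow(popB))
    stop("invalid input: both populations must be non-empty")
  pa <- buildPileup(popA, reference, contig)
  pb <- buildPileup(popB, reference, contig %||% unique(popA$contig))
  stopifnot(nrow(pa) == nrow(pb))
  fa <- pa$mismatch_frequency; fb <- pb$mismatch_frequency
  delta <- ifelse(is.na(fa) | is.na(fb), NA_real_, fa - fb)
  masked <- (is.na(fa) | fa < mask_threshold) &
            (is.na(fb) | fb < mask_threshold)
  masked <- masked | is.na(delta) |
    pa$coverage < min_coverage | pb$coverage < min_coverage
  out <- data.frame(pos = pa$pos, freq_A = fa, freq_B = fb, delta = delta,
                    masked = masked, rank = NA_integer_)
  if (any(!masked)) {
    ord <- order(-abs(out$delta[!masked]))
    out$rank[!masked][ord] <- seq_len(sum(!masked))
  }
  out
}
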