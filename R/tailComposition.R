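# Tail extraction from soft-clips, A-content filtering, composition
# classification and positional profiles.
#
# Tails are handled in RNA sense (5'->3', alphabet A/C/G/U): the soft-clip
# of a cDNA read is T-rich and ends with the adapter copy; after trimming
# the adapter the clip is reverse-complemented with T->U so that terminal
# RNA additions (e.g. uridylation) sit at the 3' end of the stored string.

.TAIL_CLASSES <- c("All-A", "Int-G", "Int-U", "Int-C",
                   "Term-G", "Term-U", "Term-C")

#' Trim the end adapter from a read end
#'
#' Aligns the adapter locally against the start (or end) of the read; when
#' the best alignment identity -- matches as a percentage of the adapter
#' length -- reaches \code{end_threshold}, the aligned span plus
#' \code{extra_end_trim} further bases is removed.
#'
#' @param read_bases base string.
#' @param adapter adapter sequence (>= 10 nt).
#' @param end_threshold minimal percent identity to trim (default 50).
#' @param extra_end_trim extra bases removed inward of the adapter match
#'   (default 0).
#' @param end which read end carries the adapter: "5p" (default) or "3p".
#' @param search_window how far into the read the adapter is searched
#'   (default 100 nt).
#' @return list(read = trimmed string, report = one-row data.frame with
#'   trimmed_bases, adapter_identity, trimmed).
#' @export
trimEndAdapter <- function(read_bases, adapter, end_threshold = 50,
                           extra_end_trim = 0L, end = c("5p", "3p"),
                           search_window = 100L) {
  end <- match.arg(end)
  if (end == "3p") {
    res <- trimEndAdapter(revComp(read_bases), revComp(adapter),
                          end_threshold, extra_end_trim, "5p", search_window)
    return(list(read = revComp(res$read), report = res$report))
  }
  res <- .trimEndAdapterBatch(read_bases, adapter, end_threshold,
                              extra_end_trim, search_window)
  list(read = res$read, report = res$report)
}

# vectorised 5'-side adapter trimming: one local alignment call for a whole
# vector of reads against the adapter
.trimEndAdapterBatch <- function(reads, adapter, end_threshold = 50,
                                 extra_end_trim = 0L, search_window = 100L) {
  if (nchar(adapter) < 10L) stop("invalid parameter: adapter shorter than 10")
  n <- nchar(reads)
  out <- reads
  ident <- numeric(length(reads))
  cut <- integer(length(reads))
  nonempty <- which(n > 0L)
  if (length(nonempty)) {
    win <- substr(reads[nonempty], 1L, pmin(n[nonempty], search_window))
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(win),
      subject = Biostrings::DNAString(adapter),
      type = "local", gapOpening = 4, gapExtension = 1)
    ident[nonempty] <- 100 * Biostrings::nmatch(pa) / nchar(adapter)
    hit <- ident >= end_threshold
    cut_at <- pmin(IRanges::end(Biostrings::pattern(pa)) + extra_end_trim,
                   n[nonempty])
    sel <- nonempty[hit[nonempty]]
    cut[sel] <- as.integer(cut_at[hit[nonempty]])
    out[sel] <- substr(reads[sel], cut[sel] + 1L, n[sel])
  }
  list(read = out,
       report = data.frame(trimmed_bases = cut, adapter_identity = ident,
                           trimmed = ident >= end_threshold & n > 0L,
                           stringsAsFactors = FALSE))
}

#' Extract the RNA-sense tail of an aligned read from its soft-clip
#'
#' Takes the soft-clipped bases on the tail side of an alignment record (the
#' side between the end adapter and the first mapped base, in cDNA
#' orientation), removes any residual adapter with
#' \code{\link{trimEndAdapter}}, and reverse-complements with T->U into RNA
#' sense. An empty clip yields NULL.
#'
#' @param alignment one-row data.frame (or list) with at least
#'   \code{read_id} and \code{clip_tail_seq} as produced by
#'   \code{\link{simulateAlignmentSet}} / \code{\link{readAlignmentsSAM}}.
#' @param adapter adapter sequence used for residual trimming.
#' @param end_threshold,extra_end_trim passed to \code{trimEndAdapter}.
#' @return one-row data.frame (read_id, rna_sense_bases, source, a_fraction)
#'   or NULL when the clip is empty.
#' @export
extractTail <- function(alignment,
                        adapter = libraryAdapters()[["end_adapter"]],
                        end_threshold = 50, extra_end_trim = 0L) {
  if (is.null(alignment$clip_tail_seq))
    stop("malformed alignment: no soft-clip information (missing CIGAR?)")
  clip <- alignment$clip_tail_seq
  if (is.na(clip) || nchar(clip) == 0) return(NULL)
  trimmed <- trimEndAdapter(clip, adapter, end_threshold, extra_end_trim)$read
  if (nchar(trimmed) == 0) return(NULL)
  rna <- cdnaToRnaSense(trimmed)
  data.frame(read_id = alignment$read_id, rna_sense_bases = rna,
             source = "softclip",
             a_fraction = 100 * baseCount(rna, "A") / nchar(rna),
             stringsAsFactors = FALSE)
}

#' A-content filter for extracted tails
#'
#' Keeps a tail only when strictly more than \code{threshold} percent of its
#' bases are A (RNA sense). Tails failing the filter are typically reads
#' whose adapter was not removed.
#'
#' @param tail one-row data.frame from \code{\link{extractTail}} (or a
#'   bare RNA-sense string).
#' @param threshold percent A required, exclusive (default 80).
#' @return logical: keep (TRUE) or discard (FALSE).
#' @export
filterAContent <- function(tail, threshold = 80) {
  seq <- if (is.character(tail)) tail else tail$rna_sense_bases
  if (is.null(seq) || is.na(seq) || nchar(seq) == 0)
    stop("invalid input: empty tail")
  a_frac <- 100 * baseCount(seq, "A") / nchar(seq)
  a_frac > threshold
}

#' Classify a tail by the composition of its last bases
#'
#' Inspects the window of the last \code{last_n} bases (the whole tail when
#' shorter). A window of pure A is "All-A". When the 3'-terminal base is not
#' A the tail is "Term-X", X being the base of the maximal terminal run.
#' Otherwise it is "Int-X", X being the most frequent non-A base in the
#' window, ties broken by proximity to the 3' end. Terminal classification
#' takes precedence over internal when both kinds of non-A bases occur.
#'
#' @param tail one-row data.frame from \code{\link{extractTail}} or an
#'   RNA-sense string.
#' @param last_n window size in nt (default 30).
#' @return factor with the 7 class levels.
#' @export
classifyTail <- function(tail, last_n = 30L) {
  seq <- if (is.character(tail)) tail else tail$rna_sense_bases
  stopifnot(nchar(seq) > 0)
  n <- nchar(seq)
  win <- substr(seq, max(1L, n - last_n + 1L), n)
  b <- strsplit(win, "")[[1]]
  lab <- if (all(b == "A")) {
    "All-A"
  } else if (b[length(b)] != "A") {
    paste0("Term-", b[length(b)])
  } else {
    nonA <- b[b != "A"]
    counts <- table(nonA)
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1L) {  # tie: base of the 3'-most tied non-A
      pos <- vapply(top, function(x) max(which(b == x)), 0)
      top <- top[which.max(pos)]
    }
    paste0("Int-", top)
  }
  factor(lab, levels = .TAIL_CLASSES)
}

#' Extract, filter and classify tails for an alignment table
#'
#' @param alignments data.frame of alignment records.
#' @param adapter,end_threshold,extra_end_trim passed to
#'   \code{\link{extractTail}}.
#' @param a_threshold A-content threshold (percent, strict).
#' @param last_n classification window (default 30).
#' @return data.frame: read_id, tail_seq (RNA sense), a_fraction, kept,
#'   class (NA for discarded tails). Reads with empty clips are absent.
#' @export
classifyTails <- function(alignments,
                          adapter = libraryAdapters()[["end_adapter"]],
                          end_threshold = 50, extra_end_trim = 0L,
                          a_threshold = 80, last_n = 30L) {
  if (is.null(alignments$clip_tail_seq))
    stop("malformed alignments: no soft-clip information (missing CIGAR?)")
  clips <- alignments$clip_tail_seq
  has_clip <- !is.na(clips) & nchar(clips) > 0
  trimmed <- .trimEndAdapterBatch(clips[has_clip], adapter, end_threshold,
                                  extra_end_trim)$read
  keep_rows <- which(has_clip)[nchar(trimmed) > 0]
  trimmed <- trimmed[nchar(trimmed) > 0]
  if (!length(keep_rows))
    return(data.frame(read_id = character(), tail_seq = character(),
                      a_fraction = numeric(), kept = logical(),
                      class = character(), stringsAsFactors = FALSE))
  rna <- cdnaToRnaSense(trimmed)
  a_frac <- 100 * baseCount(rna, "A") / nchar(rna)
  kept <- a_frac > a_threshold
  cls <- rep(NA_character_, length(rna))
  cls[kept] <- vapply(rna[kept],
                      function(s) as.character(classifyTail(s, last_n)), "")
  data.frame(read_id = alignments$read_id[keep_rows], tail_seq = rna,
             a_fraction = a_frac, kept = kept, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Positional base-composition profile of a tail set
#'
#' Aligns tails at their 3' terminus (position -1) and reports the
#' probability of each base at the last \code{last_n} positions. Tails
#' shorter than the window contribute only to the positions they cover;
#' uncovered positions carry zero weight and NA probabilities.
#'
#' @param tails character vector of RNA-sense tails, or a data.frame with a
#'   \code{tail_seq} or \code{rna_sense_bases} column.
#' @param last_n window size (default 20).
#' @return data.frame: position (-1 is the 3' terminus), n (tails covering
#'   the position), p_A, p_C, p_G, p_U; each covered position's
#'   probabilities sum to 1.
#' @export
positionalProfile <- function(tails, last_n = 20L) {
  if (is.data.frame(tails))
    tails <- tails$tail_seq %||% tails$rna_sense_bases
  tails <- tails[!is.na(tails) & nchar(tails) > 0]
  if (!length(tails)) stop("invalid input: no tails")
  bases <- c("A", "C", "G", "U")
  counts <- matrix(0L, nrow = last_n, ncol = 4L,
                   dimnames = list(NULL, bases))
  n_cov <- integer(last_n)
  for (tl in tails) {
    L <- nchar(tl)
    m <- min(L, last_n)
    b <- strsplit(substr(tl, L - m + 1L, L), "")[[1]]
    for (j in seq_len(m)) {      # j = 1 is position -1 (3' terminus)
      base <- b[m - j + 1L]
      if (base %in% bases) {
        counts[j, base] <- counts[j, base] + 1L
        n_cov[j] <- n_cov[j] + 1L
      }
    }
  }
  p <- counts / ifelse(n_cov > 0L, n_cov, NA_integer_)
  data.frame(position = -seq_len(last_n), n = n_cov,
             p_A = p[, "A"], p_C = p[, "C"], p_G = p[, "G"], p_U = p[, "U"])
}
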