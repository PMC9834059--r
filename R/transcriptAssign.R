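# 3'-end read filtering, isoform assignment and RPM quantification.
#
# Orientation convention (stated once, tested): the template-switching
# chemistry copies the RNA 3'->5', so the cDNA read starts at the RNA 3'
# end. After mapping, the read's RNA 3' end is the alignment END coordinate
# for reverse-orientation alignments (reads from "+" transcripts) and the
# alignment START coordinate for forward alignments (reads from "-"
# transcripts). All coordinates are 0-based half-open; SAM input is
# converted on read.

#' RNA 3'-end coordinate of alignment records
#'
#' @param alignments data.frame with columns strand, start, end.
#' @return integer vector of 0-based 3'-end coordinates.
#' @export
readThreePrimeEnd <- function(alignments) {
  ifelse(alignments$strand == "-", alignments$end, alignments$start)
}

# strand of the transcript a record's orientation is compatible with
.compatibleStrand <- function(aln_strand) ifelse(aln_strand == "-", "+", "-")

#' Filter incomplete reads by 3'-end agreement with annotated exon ends
#'
#' Keeps a read only when its RNA 3'-end coordinate lies within
#' \code{window} nt of an annotated exon end of a gene on the compatible
#' strand: reads whose 3' ends fall inside exons are internal degradation or
#' incomplete cDNA products. Reads on unknown contigs are dropped with a
#' warning and a logged reason.
#'
#' @param alignments alignment data.frame.
#' @param annotation a \linkS4class{TranscriptomeAnnotation}.
#' @param window maximal distance in nt, inclusive (default 10).
#' @return the kept subset of \code{alignments}, with a \code{"rejects"}
#'   attribute (data.frame read_id, reason) describing dropped reads.
#' @export
filterCompleteReads <- function(alignments, annotation, window = 10L) {
  stopifnot(is.data.frame(alignments))
  ex <- annotation@exons
  known <- as.character(GenomicRanges::seqnames(ex))
  read3p <- readThreePrimeEnd(alignments)
  want <- .compatibleStrand(alignments$strand)
  keep <- logical(nrow(alignments))
  reason <- character(nrow(alignments))
  if (!length(ex)) {
    reason[] <- "empty_annotation"
    rejects <- data.frame(read_id = alignments$read_id, reason = reason,
                          stringsAsFactors = FALSE)
    out <- alignments[0, , drop = FALSE]
    attr(out, "rejects") <- rejects
    return(out)
  }
  unknown <- !alignments$contig %in% known
  if (any(unknown)) {
    warning(sum(unknown), " read(s) on contigs absent from the annotation")
    reason[unknown] <- "unknown_contig"
  }
  # strand-resolved exon 3'-side ends, as 0-based coordinates
  plus <- as.character(GenomicRanges::strand(ex)) == "+"
  end_coord <- ifelse(plus, GenomicRanges::end(ex),
                      GenomicRanges::start(ex) - 1L)  # 0-based
  ex_tab <- data.frame(contig = as.character(GenomicRanges::seqnames(ex)),
                       strand = as.character(GenomicRanges::strand(ex)),
                       coord = end_coord, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(alignments))) {
    if (unknown[i]) next
    hit <- ex_tab$contig == alignments$contig[i] &
      ex_tab$strand == want[i] &
      abs(ex_tab$coord - read3p[i]) <= window
    if (any(hit)) keep[i] <- TRUE
    else reason[i] <- "no_exon_end_within_window"
  }
  rejects <- data.frame(read_id = alignments$read_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- alignments[keep, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Assign one read to the isoform whose annotated 3' end it matches
#'
#' Computes the distance between the read's RNA 3' end and each candidate
#' transcript's annotated 3' end; the closest candidate within
#' \code{window} nt (inclusive) wins. A tie between candidates at the same
#' minimal distance is reported as ambiguous, not double-assigned.
#'
#' @param read one-row alignment data.frame (or list with strand/start/end).
#' @param candidates transcript data.frame rows (from
#'   \code{transcripts(annotation)}) overlapping the read.
#' @param window maximal |distance| in nt, inclusive (default 10).
#' @return one-row data.frame: read_id, transcript_id (NA when unassigned),
#'   gene_id, distance, window, status (assigned / unassigned /
#'   ambiguous).
#' @export
assignToIsoform <- function(read, candidates, window = 10L) {
  read3p <- readThreePrimeEnd(as.data.frame(read))
  res <- function(txid, gene, dist, status)
    data.frame(read_id = read$read_id, transcript_id = txid, gene_id = gene,
               distance = dist, window = as.integer(window), status = status,
               stringsAsFactors = FALSE)
  if (is.null(candidates) || !nrow(candidates))
    return(res(NA_character_, NA_character_, NA_integer_, "unassigned"))
  ok <- candidates$contig == read$contig &
    candidates$strand == .compatibleStrand(read$strand)
  candidates <- candidates[ok, , drop = FALSE]
  if (!nrow(candidates))
    return(res(NA_character_, NA_character_, NA_integer_, "unassigned"))
  d <- read3p - candidates$three_prime_end
  best <- which(abs(d) == min(abs(d)))
  if (min(abs(d)) > window)
    return(res(NA_character_, NA_character_, NA_integer_, "unassigned"))
  if (length(best) > 1L) {
    genes <- unique(candidates$gene_id[best])
    return(res(NA_character_,
               if (length(genes) == 1L) genes else NA_character_,
               as.integer(d[best[1L]]), "ambiguous"))
  }
  res(candidates$transcript_id[best], candidates$gene_id[best],
      as.integer(d[best]), "assigned")
}

#' Assign all reads of an alignment table to isoforms
#'
#' @param alignments alignment data.frame.
#' @param annotation a \linkS4class{TranscriptomeAnnotation}.
#' @param window maximal |distance| in nt, inclusive (default 10).
#' @return data.frame with one row per read (columns as in
#'   \code{\link{assignToIsoform}}); assigned + unassigned + ambiguous
#'   counts always sum to the input reads.
#' @export
assignReads <- function(alignments, annotation, window = 10L) {
  tx <- annotation@transcripts
  rows <- lapply(seq_len(nrow(alignments)), function(i) {
    read <- alignments[i, ]
    cand <- tx[tx$contig == read$contig, , drop = FALSE]
    assignToIsoform(read, cand, window)
  })
  do.call(rbind, rows)
}

#' Per-gene expression as reads per million
#'
#' Counts assigned reads per gene and scales to reads per million assigned
#' reads; biotype is carried from the annotation for breakdown tables.
#'
#' @param assignments data.frame from \code{\link{assignReads}}.
#' @param annotation a \linkS4class{TranscriptomeAnnotation}.
#' @return data.frame: gene_id, biotype, count, rpm; attribute
#'   \code{"library_size"} holds the assigned-read total.
#' @export
quantifyRpm <- function(assignments, annotation) {
  ass <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (!nrow(ass)) stop("invalid input: zero assigned reads")
  counts <- table(ass$gene_id)
  tx <- annotation@transcripts
  bt <- tx$biotype[match(names(counts), tx$gene_id)]
  out <- data.frame(gene_id = names(counts), biotype = bt,
                    count = as.integer(counts),
                    rpm = 1e6 * as.integer(counts) / nrow(ass),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "library_size") <- nrow(ass)
  out
}
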