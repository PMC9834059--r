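# Readers and writers for the formats the pipeline consumes and produces.
#
# TSV outputs carry '#'-prefixed metadata header lines; coordinates in SAM
# are 1-based on disk and converted to 0-based half-open in memory; tails
# are written RNA-sense.

#' Write squiggles to a plain-text per-read signal container
#'
#' One row per read: read_id, sampling_rate, basecalled_length and the
#' current samples as a comma-joined float array, printed with enough
#' digits to round-trip exactly.
#'
#' @param squiggles list of \linkS4class{Squiggle}.
#' @param path output file.
#' @export
writeSignalContainer <- function(squiggles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#tailcapR signal container v1", con)
  writeLines("read_id\tsampling_rate\tbasecalled_length\tsamples", con)
  for (sq in squiggles) {
    writeLines(paste(sq@read_id, format(sq@sampling_rate),
                     sq@basecalled_length,
                     paste(sprintf("%.17g", sq@samples), collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a signal container written by \code{\link{writeSignalContainer}}
#'
#' @param path input file.
#' @return list of \linkS4class{Squiggle}.
#' @export
readSignalContainer <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines) || !startsWith(lines[1], "read_id"))
    stop("not a signal container: ", path)
  lines <- lines[-1]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) stop("malformed signal record: ", substr(ln, 1, 40))
    methods::new("Squiggle", read_id = f[1],
                 samples = as.numeric(strsplit(f[4], ",", fixed = TRUE)[[1]]),
                 sampling_rate = as.numeric(f[2]),
                 basecalled_length = as.integer(f[3]))
  })
}

#' Reconstruct cDNA-orientation read sequences from alignment records
#'
#' @param alignments alignment data.frame.
#' @return named character vector of read sequences (5'->3' cDNA sense:
#'   soft-clip first, then the insert).
#' @export
readSequencesFromAlignments <- function(alignments) {
  ins <- ifelse(alignments$strand == "-", revComp(alignments$aligned_seq),
                alignments$aligned_seq)
  stats::setNames(paste0(alignments$clip_tail_seq, ins), alignments$read_id)
}

#' Write reads as FASTQ
#'
#' @param seqs named character vector of read sequences.
#' @param path output file.
#' @export
writeReadsFastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    strrep("I", w), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ with validation
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
readReadsFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub(" .*", "", lines[seq(1, length(lines), 4)]))
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("FASTQ record with sequence/quality length mismatch: ",
         ids[which(bad)[1]])
  stats::setNames(seqs, ids)
}

#' Write alignment records as SAM
#'
#' Soft-clips are encoded in the CIGAR; reverse-orientation records store
#' the reverse-complemented read, so the tail-side clip appears at the
#' right end of SEQ.
#'
#' @param alignments alignment data.frame.
#' @param path output file.
#' @param contig_lengths named integer vector for the @SQ header lines
#'   (default: max alignment end per contig).
#' @export
writeAlignmentsSAM <- function(alignments, path, contig_lengths = NULL) {
  if (is.null(contig_lengths))
    contig_lengths <- tapply(alignments$end, alignments$contig, max)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ct in names(contig_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ct,
                       as.integer(contig_lengths[[ct]])), con)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    M <- a$end - a$start
    if (a$strand == "+") {
      cigar <- paste0(if (a$clip_tail > 0) paste0(a$clip_tail, "S") else "",
                      M, "M")
      seq <- paste0(a$clip_tail_seq, a$aligned_seq)
      flag <- 0L
    } else {
      cigar <- paste0(M, "M",
                      if (a$clip_tail > 0) paste0(a$clip_tail, "S") else "")
      seq <- paste0(a$aligned_seq,
                    if (nchar(a$clip_tail_seq)) revComp(a$clip_tail_seq)
                    else "")
      flag <- 16L
    }
    writeLines(paste(a$read_id, flag, a$contig, a$start + 1L, 60L, cigar,
                     "*", 0L, 0L, seq, strrep("I", nchar(seq)),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Parses the subset of SAM the simulator emits (soft-clips + matches,
#' substitution-only alignments) into the in-memory alignment table,
#' resolving the tail-side soft-clip back to cDNA orientation.
#'
#' @param path input SAM file.
#' @return alignment data.frame (see \code{\link{simulateAlignmentSet}}).
#' @export
readAlignmentsSAM <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record: ", substr(ln, 1, 40))
    flag <- as.integer(f[2])
    cigar <- f[6]
    seq <- f[10]
    start <- as.integer(f[4]) - 1L
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    kinds <- sub("\\d+", "", ops)
    if (!all(kinds %in% c("M", "S")))
      stop("unsupported CIGAR in record ", f[1], ": ", cigar)
    M <- sum(lens[kinds == "M"])
    left_s <- if (kinds[1] == "S") lens[1] else 0L
    right_s <- if (kinds[length(kinds)] == "S") lens[length(kinds)] else 0L
    if (bitwAnd(flag, 16L) > 0L) {
      strand <- "-"
      clip_seq <- if (right_s > 0)
        revComp(substr(seq, nchar(seq) - right_s + 1L, nchar(seq))) else ""
      aligned <- substr(seq, left_s + 1L, left_s + M)
      clip <- right_s; other <- left_s
    } else {
      strand <- "+"
      clip_seq <- if (left_s > 0) substr(seq, 1L, left_s) else ""
      aligned <- substr(seq, left_s + 1L, left_s + M)
      clip <- left_s; other <- right_s
    }
    data.frame(read_id = f[1], contig = f[3], strand = strand,
               start = start, end = start + M, clip_tail = clip,
               clip_other = other, clip_tail_seq = clip_seq,
               aligned_seq = aligned, mapped = f[3] != "*",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write annotation as GTF
#'
#' @param annotation a \linkS4class{TranscriptomeAnnotation}.
#' @param path output file.
#' @export
writeAnnotationGTF <- function(annotation, path) {
  ex <- annotation@exons
  S4Vectors::mcols(ex)$source <- "tailcapR"
  S4Vectors::mcols(ex)$type <- "exon"
  tx <- annotation@transcripts
  S4Vectors::mcols(ex)$gene_biotype <-
    tx$biotype[match(S4Vectors::mcols(ex)$transcript_id, tx$transcript_id)]
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Read annotation from GTF
#'
#' Exon rows are collected per transcript (sorted, with a warning when they
#' arrive out of order) and strand-resolved 3' ends are derived from the
#' extreme exon boundaries.
#'
#' @param path GTF file.
#' @param reference optional \code{DNAStringSet} of contig sequences.
#' @return a \linkS4class{TranscriptomeAnnotation}.
#' @export
readAnnotationGTF <- function(path, reference = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (is.unsorted(GenomicRanges::start(gr))) {
    warning("exons out of order in ", path, "; sorting")
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  md <- S4Vectors::mcols(gr)
  key <- md$transcript_id
  tx <- lapply(split(seq_along(gr), key), function(ix) {
    g <- gr[ix]
    strand <- as.character(GenomicRanges::strand(g))[1]
    tpe <- if (strand == "+") max(GenomicRanges::end(g))
           else min(GenomicRanges::start(g)) - 1L
    data.frame(transcript_id = md$transcript_id[ix[1]],
               gene_id = md$gene_id[ix[1]],
               biotype = (md$gene_biotype %||% rep("unknown", length(gr)))[ix[1]] %||% "unknown",
               contig = as.character(GenomicRanges::seqnames(g))[1],
               strand = strand, three_prime_end = as.integer(tpe),
               stringsAsFactors = FALSE)
  })
  txdf <- do.call(rbind, tx)
  rownames(txdf) <- NULL
  txdf$biotype[is.na(txdf$biotype)] <- "unknown"
  methods::new("TranscriptomeAnnotation", transcripts = txdf, exons = gr,
               reference = reference %||% Biostrings::DNAStringSet())
}

#' Write annotated 3' ends as BED
#'
#' One zero-length-style BED feature (width 1) per transcript 3' end.
#'
#' @param annotation a \linkS4class{TranscriptomeAnnotation}.
#' @param path output file.
#' @export
writeThreePrimeEndsBED <- function(annotation, path) {
  tx <- annotation@transcripts
  start0 <- ifelse(tx$strand == "+", tx$three_prime_end - 1L,
                   tx$three_prime_end)
  gr <- GenomicRanges::GRanges(tx$contig,
                               IRanges::IRanges(start = start0 + 1L,
                                                width = 1L),
                               strand = tx$strand,
                               name = tx$transcript_id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a data.frame as TSV with metadata header lines
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named character vector written as '# key: value' lines.
#' @export
writeTsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{writeTsv}}
#'
#' @param path input file.
#' @return data.frame (metadata lines are skipped).
#' @export
readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
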