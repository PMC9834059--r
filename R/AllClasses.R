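#' PoreModel: k-mer current level table
#'
#' A synthetic pore chemistry: every k-mer over \{A,C,G,T\} is assigned a mean
#' current level (arbitrary pA-like units) and a level standard deviation.
#' Levels are constructed so that (i) any two k-mers adjacent in the de Bruijn
#' sense (one can follow the other in a sequence) have distinct levels, making
#' base transitions visible as current steps, and (ii) T-rich and A-rich
#' k-mers -- the homopolymer context of cDNA polyA/polyT tails -- sit on
#' plateaus far outside the remaining level range, so tail segments are
#' low-variance stretches clearly separated from the adapter levels.
#'
#' @slot k k-mer length.
#' @slot levels named numeric vector, mean level per k-mer.
#' @slot sds named numeric vector, level standard deviation per k-mer.
#' @slot seed integer seed the table was built from.
#' @exportClass PoreModel
setClass("PoreModel",
  representation(k = "integer", levels = "numeric", sds = "numeric",
                 seed = "integer"))

setValidity("PoreModel", function(object) {
  km <- allKmers(object@k)
  msg <- character()
  if (length(object@levels) != length(km) ||
      !setequal(names(object@levels), km))
    msg <- c(msg, sprintf("levels must have exactly one entry per %d-mer",
                          object@k))
  if (any(object@sds <= 0)) msg <- c(msg, "all level sds must be > 0")
  homo <- vapply(c("A", "C", "G", "T"),
                 function(b) strrep(b, object@k), "")
  hl <- object@levels[homo]
  if (!anyNA(hl) && anyDuplicated(hl))
    msg <- c(msg, "homopolymer k-mers must map to distinct levels")
  if (length(msg)) msg else TRUE
})

#' Squiggle: one read's raw current trace
#'
#' @slot read_id read identifier.
#' @slot samples ordered current samples.
#' @slot sampling_rate samples per second (metadata only).
#' @slot basecalled_length number of bases called for the read (0 if no
#'   base-called read exists yet).
#' @exportClass Squiggle
setClass("Squiggle",
  representation(read_id = "character", samples = "numeric",
                 sampling_rate = "numeric", basecalled_length = "integer"))

setValidity("Squiggle", function(object) {
  msg <- character()
  if (length(object@samples) == 0) msg <- c(msg, "samples must be non-empty")
  if (object@basecalled_length < 0)
    msg <- c(msg, "basecalled_length must be >= 0")
  if (length(msg)) msg else TRUE
})

#' NormalizedSignal: robustly scaled current trace
#'
#' @slot read_id read identifier.
#' @slot z normalized values, (x - median) / (1.4826 * MAD).
#' @slot center the median of the raw samples.
#' @slot scale the MAD-based (or fallback sd) scale; always > 0.
#' @exportClass NormalizedSignal
setClass("NormalizedSignal",
  representation(read_id = "character", z = "numeric",
                 center = "numeric", scale = "numeric"))

setValidity("NormalizedSignal", function(object) {
  if (object@scale <= 0) "scale must be > 0" else TRUE
})

#' TailSegment: the located tail region of a signal
#'
#' Half-open sample interval [start, end) in 0-based sample coordinates,
#' together with the detected adapter boundary and segment statistics.
#'
#' @slot start,end half-open 0-based sample interval of the tail.
#' @slot mean_level mean normalized level inside the segment.
#' @slot variance within-segment variance of the normalized signal.
#' @slot boundary 0-based sample index of the detected adapter-stub boundary.
#' @exportClass TailSegment
setClass("TailSegment",
  representation(start = "integer", end = "integer", mean_level = "numeric",
                 variance = "numeric", boundary = "integer"))

setValidity("TailSegment", function(object) {
  if (object@start < 0 || object@start >= object@end)
    "need 0 <= start < end" else TRUE
})

#' TailCall: per-read tail length estimate
#'
#' @slot read_id read identifier.
#' @slot tail_samples samples attributed to the tail segment.
#' @slot rate translocation rate, samples per nucleotide (NA when no tail).
#' @slot tail_length_nt estimated tail length in nucleotides (non-negative
#'   real; 0 when status is "zero_tail").
#' @slot status one of "called", "zero_tail", "unreliable".
#' @exportClass TailCall
setClass("TailCall",
  representation(read_id = "character", tail_samples = "integer",
                 rate = "numeric", tail_length_nt = "numeric",
                 status = "character"))

setValidity("TailCall", function(object) {
  msg <- character()
  if (!object@status %in% c("called", "zero_tail", "unreliable"))
    msg <- c(msg, "status must be called, zero_tail or unreliable")
  if (object@status == "zero_tail" && object@tail_length_nt != 0)
    msg <- c(msg, "zero_tail calls must have tail_length_nt == 0")
  if (object@status == "called" && object@tail_length_nt < 0)
    msg <- c(msg, "called tail_length_nt must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TranscriptomeAnnotation: transcripts, exons and (optionally) sequence
#'
#' Container tying together a transcript table (with strand-resolved 3' end
#' coordinates), an exon \code{GRanges} and an optional reference
#' \code{DNAStringSet}. All coordinates are 0-based half-open internally;
#' \code{three_prime_end} is the coordinate of the annotated RNA 3' terminus:
#' the half-open exon end for "+" transcripts and the 0-based exon start for
#' "-" transcripts.
#'
#' @slot transcripts data.frame with columns transcript_id, gene_id, biotype,
#'   contig, strand, three_prime_end.
#' @slot exons \code{GRanges} of exons carrying transcript_id/gene_id.
#' @slot reference \code{DNAStringSet} of contig sequences (may be empty).
#' @exportClass TranscriptomeAnnotation
setClass("TranscriptomeAnnotation",
  representation(transcripts = "data.frame", exons = "GRanges",
                 reference = "DNAStringSet"))

setValidity("TranscriptomeAnnotation", function(object) {
  tx <- object@transcripts
  need <- c("transcript_id", "gene_id", "biotype", "contig", "strand",
            "three_prime_end")
  msg <- character()
  if (!all(need %in% names(tx)))
    msg <- c(msg, paste("transcripts must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tx$transcript_id))
      msg <- c(msg, "transcript_id values must be unique")
    if (!all(tx$strand %in% c("+", "-")))
      msg <- c(msg, "transcript strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoreModel", function(object) {
  cat(sprintf("PoreModel: %d-mer table, %d levels (seed %d)\n",
              object@k, length(object@levels), object@seed))
  rng <- range(object@levels)
  cat(sprintf("  level range %.1f..%.1f, sd range %.2f..%.2f\n",
              rng[1], rng[2], min(object@sds), max(object@sds)))
})

setMethod("show", "Squiggle", function(object) {
  cat(sprintf("Squiggle %s: %d samples @ %g Hz, %d bases called\n",
              object@read_id, length(object@samples), object@sampling_rate,
              object@basecalled_length))
})

setMethod("show", "TailSegment", function(object) {
  cat(sprintf("TailSegment [%d, %d) (%d samples), boundary %d, var %.2g\n",
              object@start, object@end, object@end - object@start,
              object@boundary, object@variance))
})

setMethod("show", "TailCall", function(object) {
  cat(sprintf("TailCall %s: %.2f nt (%d samples at %.2f samples/nt) [%s]\n",
              object@read_id, object@tail_length_nt, object@tail_samples,
              object@rate, object@status))
})

setMethod("show", "TranscriptomeAnnotation", function(object) {
  cat(sprintf(
    "TranscriptomeAnnotation: %d transcripts / %d genes, %d exons, %d contigs\n",
    nrow(object@transcripts), length(unique(object@transcripts$gene_id)),
    length(object@exons), length(object@reference)))
})

# ---- accessors ----

#' @describeIn Squiggle-class number of samples
#' @param x a Squiggle
#' @export
sampleCount <- function(x) length(x@samples)

#' Accessors for package classes
#'
#' Small getter functions used instead of direct slot access.
#'
#' @param x object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
readId <- function(x) x@read_id

#' @rdname accessors
#' @export
signalSamples <- function(x) x@samples

#' @rdname accessors
#' @export
poreLevels <- function(x) x@levels

#' @rdname accessors
#' @export
poreSds <- function(x) x@sds

#' @rdname accessors
#' @export
kmerLength <- function(x) x@k

#' @rdname accessors
#' @export
tailLengthNt <- function(x) x@tail_length_nt

#' @rdname accessors
#' @export
tailStatus <- function(x) x@status

#' @rdname accessors
#' @export
transcripts <- function(x) x@transcripts

#' @rdname accessors
#' @export
exons <- function(x) x@exons

#' @rdname accessors
#' @export
referenceSeqs <- function(x) x@reference
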