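# Synthetic annotation and soft-clipped alignment simulation.
#
# Alignment records model template-switched cDNA reads after mapping: the
# aligned portion covers the reference 3' end of a transcript (up to a
# controlled offset) and the unaligned tail + optional adapter remnant is a
# soft-clip on the read side that corresponds to the RNA 3' end. For a "+"
# transcript the cDNA read maps in reverse orientation, so its RNA 3' end is
# the right (end) alignment coordinate; for a "-" transcript it maps forward
# and the RNA 3' end is the left (start) coordinate.

#' Generate a small synthetic transcriptome with annotation
#'
#' Builds one contig of random sequence and a set of single-exon genes on
#' both strands, each with one or more isoforms whose 3' ends are separated
#' by a controlled distance (so 3' end isoform assignment is exercised).
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene isoforms per gene (recycled).
#' @param isoform_end_gap distance in nt between consecutive isoform 3' ends
#'   of a gene (default 60).
#' @param gene_length transcript span in nt (default 400).
#' @param spacing gap between genes (default 300).
#' @param biotypes biotype labels assigned round-robin to genes.
#' @param seed integer seed.
#' @return a \linkS4class{TranscriptomeAnnotation}.
#' @export
makeTestTranscriptome <- function(n_genes = 6L, isoforms_per_gene = 2L,
                                  isoform_end_gap = 60L, gene_length = 400L,
                                  spacing = 300L,
                                  biotypes = c("protein_coding", "lincRNA"),
                                  seed = 1L) {
  stopifnot(n_genes >= 1L, gene_length > isoform_end_gap * 2L)
  withSeed(seed, {
    iso_n <- rep_len(isoforms_per_gene, n_genes)
    contig_len <- n_genes * (gene_length + spacing) + 2L * spacing
    contig <- paste(sample(c("A", "C", "G", "T"), contig_len, TRUE,
                           prob = c(0.28, 0.25, 0.25, 0.22)), collapse = "")
    tx <- list(); ex <- list()
    for (g in seq_len(n_genes)) {
      gstart <- spacing + (g - 1L) * (gene_length + spacing)  # 0-based
      gend <- gstart + gene_length
      strand <- if (g %% 2L == 1L) "+" else "-"
      gene_id <- sprintf("gene%02d", g)
      biotype <- biotypes[(g - 1L) %% length(biotypes) + 1L]
      for (i in seq_len(iso_n[g])) {
        txid <- sprintf("%s.t%d", gene_id, i)
        if (strand == "+") {
          s <- gstart; e <- gend - (i - 1L) * isoform_end_gap
          tpe <- e
        } else {
          s <- gstart + (i - 1L) * isoform_end_gap; e <- gend
          tpe <- s
        }
        tx[[txid]] <- data.frame(
          transcript_id = txid, gene_id = gene_id, biotype = biotype,
          contig = "chrS", strand = strand, three_prime_end = tpe,
          tx_start = s, tx_end = e, stringsAsFactors = FALSE)
        ex[[txid]] <- data.frame(contig = "chrS", start = s, end = e,
                                 strand = strand, transcript_id = txid,
                                 gene_id = gene_id, stringsAsFactors = FALSE)
      }
    }
    txdf <- do.call(rbind, tx); rownames(txdf) <- NULL
    exdf <- do.call(rbind, ex)
    exons <- GenomicRanges::GRanges(
      seqnames = exdf$contig,
      ranges = IRanges::IRanges(start = exdf$start + 1L, end = exdf$end),
      strand = exdf$strand,
      transcript_id = exdf$transcript_id, gene_id = exdf$gene_id)
    ref <- Biostrings::DNAStringSet(stats::setNames(contig, "chrS"))
    methods::new("TranscriptomeAnnotation", transcripts = txdf,
                 exons = exons, reference = ref)
  })
}

#' Describe a tail population for simulation
#'
#' @param classes composition class labels, among "All-A", "Term-G",
#'   "Term-U", "Term-C", "Int-G", "Int-U", "Int-C".
#' @param lengths designed tail lengths (nt, recycled against classes).
#' @param probs sampling probabilities (recycled, normalized).
#' @param n_mod number of non-A bases for Term-/Int- classes (default 3).
#' @return data.frame used as \code{tail_spec} by
#'   \code{\link{simulateAlignmentSet}}.
#' @export
tailSpec <- function(classes = "All-A", lengths = 30L, probs = 1,
                     n_mod = 3L) {
  ok <- c("All-A", "Term-G", "Term-U", "Term-C", "Int-G", "Int-U", "Int-C")
  if (!all(classes %in% ok))
    stop("unknown tail class; use one of: ", paste(ok, collapse = ", "))
  n <- max(length(classes), length(lengths), length(probs))
  data.frame(class = rep_len(classes, n),
             length = as.integer(rep_len(lengths, n)),
             prob = rep_len(probs, n) / sum(rep_len(probs, n)),
             n_mod = as.integer(rep_len(n_mod, n)),
             stringsAsFactors = FALSE)
}

# build an RNA-sense tail string for a designed class
.buildRnaTail <- function(class, len, n_mod) {
  if (len <= 0L) return("")
  if (class == "All-A") return(strrep("A", len))
  base <- sub(".*-", "", class)
  base <- chartr("U", "U", base)
  m <- min(n_mod, len)
  if (startsWith(class, "Term")) {
    return(paste0(strrep("A", len - m), strrep(base, m)))
  }
  # internal: non-A singletons at spread positions, never terminal
  tail <- rep("A", len)
  if (len >= 3L) {
    pos <- unique(pmin(pmax(round(seq(2, len - 1, length.out = m)), 2L),
                       len - 1L))
    tail[pos] <- base
  }
  paste(tail, collapse = "")
}

.substituteErrors <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    alpha <- c("A", "C", "G", "T")
    repl <- vapply(bases[hit],
                   function(b) sample(setdiff(alpha, b), 1L), "")
    bases[hit] <- repl
  }
  paste(bases, collapse = "")
}

#' Simulate soft-clipped alignment records with known truth
#'
#' Draws reads from the transcripts of \code{annotation}: each read aligns
#' over the 3'-terminal part of its transcript with a controlled 3' end
#' offset, and carries its designed tail (in cDNA sense, preceded by an
#' optional end-adapter remnant) as a soft-clip on the RNA 3' end side.
#' Substitution errors are applied to aligned and clipped bases at
#' \code{error_rate}; optional mismatch hotspots raise the substitution
#' rate at chosen reference positions (for modification profiling).
#'
#' @param annotation a \linkS4class{TranscriptomeAnnotation} with sequence.
#' @param n_reads number of reads (> 0).
#' @param tail_spec data.frame from \code{\link{tailSpec}}.
#' @param error_rate per-base substitution probability in [0, 0.2).
#' @param seed integer seed.
#' @param offsets integer vector the signed 3' end offset is drawn from
#'   uniformly (default 0, reads end exactly at the annotated end).
#' @param aligned_span range of aligned lengths, nt (default c(80, 150)).
#' @param adapter_remnant_prob probability that the full end adapter is left
#'   on the clip, to exercise trimming (default 0.5).
#' @param transcript_weights optional named sampling weights per transcript.
#' @param hotspots optional data.frame(pos, rate): 0-based reference
#'   positions whose per-read substitution probability is raised to `rate`.
#' @return list with \code{alignments} (data.frame: read_id, contig, strand,
#'   start, end, clip_tail, clip_other, clip_tail_seq, aligned_seq, mapped)
#'   and \code{truth} (data.frame: read_id, transcript_id, gene_id,
#'   tail_rna, class, offset, design_length). Coordinates 0-based half-open;
#'   \code{strand} is the alignment orientation (opposite the transcript
#'   strand for this chemistry).
#' @export
simulateAlignmentSet <- function(annotation, n_reads, tail_spec = tailSpec(),
                                 error_rate = 0, seed = 1L, offsets = 0L,
                                 aligned_span = c(80L, 150L),
                                 adapter_remnant_prob = 0.5,
                                 transcript_weights = NULL,
                                 hotspots = NULL) {
  if (!methods::is(annotation, "TranscriptomeAnnotation"))
    stop("'annotation' must be a TranscriptomeAnnotation")
  if (!is.numeric(n_reads) || n_reads <= 0) stop("'n_reads' must be > 0")
  if (error_rate < 0 || error_rate >= 0.2)
    stop("'error_rate' must be in [0, 0.2)")
  tx <- annotation@transcripts
  if (!nrow(tx)) stop("'annotation' is empty")
  ref <- annotation@reference
  adapter <- libraryAdapters()[["end_adapter"]]
  n_reads <- as.integer(n_reads)
  withSeed(seed, {
    w <- if (is.null(transcript_weights)) rep(1, nrow(tx)) else
      transcript_weights[tx$transcript_id]
    pick_tx <- sample.int(nrow(tx), n_reads, TRUE, prob = w)
    pick_tail <- sample.int(nrow(tail_spec), n_reads, TRUE,
                            prob = tail_spec$prob)
    off <- sample(offsets, n_reads, TRUE)
    spans <- sample(seq(aligned_span[1], aligned_span[2]), n_reads, TRUE)
    remnant <- stats::runif(n_reads) < adapter_remnant_prob
    aln <- vector("list", n_reads); tru <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      t <- tx[pick_tx[i], ]
      contig_seq <- ref[[t$contig]]
      clen <- length(contig_seq)
      ts <- tail_spec[pick_tail[i], ]
      tail_rna <- .buildRnaTail(ts$class, ts$length, ts$n_mod)
      M <- spans[i]
      if (t$strand == "+") {
        e <- min(max(t$three_prime_end + off[i], M + 1L), clen)
        s <- e - M
        aln_strand <- "-"
        read3p <- e
      } else {
        s <- max(min(t$three_prime_end + off[i], clen - M - 1L), 0L)
        e <- s + M
        aln_strand <- "+"
        read3p <- s
      }
      aligned <- as.character(Biostrings::subseq(contig_seq, s + 1L, e))
      # per-base substitution, optionally with hotspot sites
      if (!is.null(hotspots) && nrow(hotspots)) {
        bases <- strsplit(aligned, "")[[1]]
        rel <- hotspots$pos - s
        p <- rep(error_rate, length(bases))
        inb <- rel >= 0L & rel < length(bases)
        p[rel[inb] + 1L] <- hotspots$rate[inb]
        hit <- stats::runif(length(bases)) < p
        if (any(hit)) {
          alpha <- c("A", "C", "G", "T")
          bases[hit] <- vapply(bases[hit],
                               function(b) sample(setdiff(alpha, b), 1L), "")
        }
        aligned <- paste(bases, collapse = "")
      } else {
        aligned <- .substituteErrors(aligned, error_rate)
      }
      tail_cdna <- if (nchar(tail_rna)) rnaToCdnaSense(tail_rna) else ""
      clip <- paste0(if (remnant[i]) adapter else "", tail_cdna)
      clip <- .substituteErrors(clip, error_rate)
      aln[[i]] <- data.frame(
        read_id = sprintf("sim_%05d", i), contig = t$contig,
        strand = aln_strand, start = s, end = e,
        clip_tail = nchar(clip), clip_other = 0L,
        clip_tail_seq = clip, aligned_seq = aligned, mapped = TRUE,
        stringsAsFactors = FALSE)
      tru[[i]] <- data.frame(
        read_id = sprintf("sim_%05d", i), transcript_id = t$transcript_id,
        gene_id = t$gene_id, tail_rna = tail_rna, class = ts$class,
        offset = off[i], design_length = ts$length, read3p = read3p,
        stringsAsFactors = FALSE)
    }
    list(alignments = do.call(rbind, aln), truth = do.call(rbind, tru))
  })
}
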