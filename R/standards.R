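# Synthetic cDNA tail standards and library oligos.
#
# Twelve synthetic cDNA ultramers are used as ground truth for tail length
# estimation (tails of 0/15/30/60/90/120 T in cDNA sense) and tail
# composition analysis (30-nt tails carrying terminal U/C/G or internal G
# additions in RNA sense). Each standard is laid out as
# [31-nt end adapter][tail][insert]; the tail in cDNA sense is the reverse
# complement of the RNA-sense tail, so terminal RNA additions appear at the
# tail 5' side of the cDNA string, right after the adapter.

# body of the D_DNA end adapter (terminal randomized N dropped)
.END_ADAPTER <- "CTTCCGATCACTTGCCTGTCGCTCTATCTTC"

# RNA oligo annealed to the adapter during template switching (RNA bases)
.R_RNA <- "GAAGAUAGAGCGACAGGCAAGUGAUCGGAAG"

# complementary oligo used for sequencing-adapter ligation
.COMP_A_DNA <- "GAAGATAGAGCGACAGGCAAGTGATCGGAAGA"

.STANDARD_SEQS <- c(
  cDNA_pA_standard_0 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATGAAAAATGCTTGTTTGCAACCCTATATAGAA",
  cDNA_pA_standard_15 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATGAAAAATGCTTGTTTG",
  cDNA_pA_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG",
  cDNA_pA_standard_60 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAG",
  cDNA_pA_standard_90 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGG",
  cDNA_pA_standard_120 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATT",
  cDNA_p29A_pU1_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCATTTTTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG",
  cDNA_p27A_pU3_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCAAATTTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG",
  cDNA_p25A_pU5_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCAAAAATTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG",
  cDNA_p25A_pC5_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCGGGGGTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG",
  cDNA_p25A_pG5_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCCCCCCTTTTTTTTTTTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG",
  cDNA_pA_internalG_standard_30 = "CTTCCGATCACTTGCCTGTCGCTCTATCTTCTTTTCTTTTCTTTTCTTTTTTTTTTTTTTTGTAAATAGAAATAGACTAGCTCCACTTTTAAGAATTATTTATGCAATTAAATACATGGGTGACCAAAAGAGCGGGCGGATACACGCGTCACCACAAGCAGAATAAAAGGTAAACCTGAAATTGTTTTAACATAAAATG"
)

.STANDARD_TAIL_NT <- c(0L, 15L, 30L, 60L, 90L, 120L, 30L, 30L, 30L, 30L, 30L, 30L)
.STANDARD_SERIES <- c(rep("length_series", 6), rep("composition_series", 6))

#' Library adapter oligos
#'
#' Returns the oligo sequences of the end-capture library chemistry: the
#' 31-nt body of the end adapter ligated next to the RNA 3' end (whose copy
#' starts every cDNA read), the RNA oligo it is pre-annealed to, and the
#' complementary oligo used for sequencing-adapter ligation.
#'
#' @return named character vector with elements \code{end_adapter},
#'   \code{rna_oligo}, \code{comp_oligo}.
#' @export
#' @examples
#' nchar(libraryAdapters()[["end_adapter"]])  # 31
libraryAdapters <- function() {
  c(end_adapter = .END_ADAPTER, rna_oligo = .R_RNA, comp_oligo = .COMP_A_DNA)
}

#' Registry of the synthetic cDNA tail standards
#'
#' The twelve synthetic cDNA standards with known tail length and
#' composition. Six form the tail length series (designed tails of 0, 15,
#' 30, 60, 90 and 120 nt) and six the composition series (30-nt tails that
#' are pure A, carry 1/3/5 terminal U, 5 terminal C or G, or internal Gs, in
#' RNA sense).
#'
#' @return data.frame with one row per standard: \code{name},
#'   \code{full_sequence} (cDNA sense), \code{adapter_prefix},
#'   \code{design_tail_length}, \code{design_tail_composition} (cDNA-sense
#'   tail between adapter and insert), \code{design_tail_rna} (RNA-sense
#'   tail), \code{series}.
#' @export
#' @examples
#' reg <- standardsRegistry()
#' subset(reg, series == "length_series")$design_tail_length
standardsRegistry <- function() {
  alen <- nchar(.END_ADAPTER)
  tail_cdna <- substr(.STANDARD_SEQS, alen + 1L, alen + .STANDARD_TAIL_NT)
  data.frame(
    name = names(.STANDARD_SEQS),
    full_sequence = unname(.STANDARD_SEQS),
    adapter_prefix = .END_ADAPTER,
    design_tail_length = .STANDARD_TAIL_NT,
    design_tail_composition = unname(tail_cdna),
    design_tail_rna = ifelse(.STANDARD_TAIL_NT > 0,
                             cdnaToRnaSense(unname(tail_cdna)), ""),
    series = .STANDARD_SERIES,
    stringsAsFactors = FALSE
  )
}

#' Locate the tail region of a cDNA-sense sequence
#'
#' Finds the T-rich tail between the end adapter and the insert of a
#' cDNA-sense read or standard: starting right after the adapter prefix, an
#' optional leading non-T block of at most 5 bases (the cDNA image of
#' terminal RNA additions) must be followed by at least 5 consecutive T;
#' the tail then extends through T runs, tolerating internal non-T blocks of
#' at most 2 bases when at least 3 T follow, and ends at the last T before a
#' violation. Returns NULL when no tail is present directly after the
#' adapter.
#'
#' @param sequence cDNA-sense base string beginning with the adapter.
#' @param adapter adapter prefix (default the library end adapter).
#' @return integer vector c(start, end), a 0-based half-open base interval
#'   of the tail within \code{sequence}, or NULL if there is no tail.
#' @export
detectTailRegion <- function(sequence, adapter = libraryAdapters()[["end_adapter"]]) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  off <- if (startsWith(sequence, adapter)) nchar(adapter) else 0L
  bases <- strsplit(substr(sequence, off + 1L, nchar(sequence)), "")[[1]]
  n <- length(bases)
  if (n == 0) return(NULL)
  isT <- bases == "T"
  i <- 1L
  # optional leading non-T block (<= 5) followed by >= 5 consecutive T
  if (!isT[1]) {
    lead <- 0L
    while (i <= n && !isT[i] && lead < 5L) { i <- i + 1L; lead <- lead + 1L }
    if (i > n || !isT[i]) return(NULL)
    if (i + 4L > n || !all(isT[i:(i + 4L)])) return(NULL)
  }
  if (!isT[i]) return(NULL)
  last_t <- 0L
  j <- i
  while (j <= n) {
    if (isT[j]) { last_t <- j; j <- j + 1L; next }
    # internal non-T block: <= 2 bases then >= 3 consecutive T
    blk <- 0L
    while (j <= n && !isT[j] && blk < 2L) { j <- j + 1L; blk <- blk + 1L }
    if (j + 2L > n || !all(isT[j:(j + 2L)])) break
  }
  if (last_t == 0L) return(NULL)
  c(off, off + last_t)  # 0-based half-open, tail starts right after adapter
}
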