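# ten 20-nt reads on a 30-nt reference, hand-built
ref30 <- paste(rep(c("A", "C", "G", "T", "A", "G"), 5), collapse = "")

mk_reads <- function(n, start, end, mutate_at = integer(), mutate_in = integer()) {
  seqs <- vapply(seq_len(n), function(i) {
    b <- strsplit(substr(ref30, start + 1, end), "")[[1]]
    if (i %in% mutate_in)
      for (p in mutate_at) b[p - start] <- if (b[p - start] == "A") "G" else "A"
    paste(b, collapse = "")
  }, "")
  data.frame(read_id = sprintf("r%02d", seq_len(n)), contig = "ref",
             strand = "-", start = start, end = end, clip_tail = 0L,
             clip_other = 0L, clip_tail_seq = "", aligned_seq = seqs,
             mapped = TRUE, stringsAsFactors = FALSE)
}

test_that("pileup counting, conservation and drop-off bookkeeping", {
  # 3 of 10 reads substituted at 0-based site 5
  reads <- mk_reads(10, 2L, 22L, mutate_at = 6L, mutate_in = 1:3)
  pil <- buildPileup(reads, ref30)
  expect_equal(pil$mismatch_frequency[pil$pos == 5], 0.3)
  expect_equal(pil$coverage[pil$pos == 5], 10L)
  # conservation at every site
  expect_true(all(pil$n_A + pil$n_C + pil$n_G + pil$n_T + pil$n_del ==
                    pil$coverage))
  # sites nobody reaches are missing, not zero
  expect_true(all(is.na(pil$mismatch_frequency[pil$coverage == 0])))
  expect_true(all(pil$match + pil$mismatch <= pil$coverage))
  # one drop-off per read, at the RT-termination side
  expect_equal(sum(pil$dropoff), 10L)
  expect_equal(pil$dropoff[pil$pos == 2], 10L)  # '-' strand: start side
  expect_error(buildPileup(reads[0, ], ref30), "no alignments")
})

test_that("uniform substitution noise gives the binomial mismatch level", {
  anno <- fixture_annotation()
  sim <- simulateAlignmentSet(anno, 300, tailSpec("All-A", 20),
                              error_rate = 0.02, seed = 41)
  pil <- buildPileup(sim$alignments, referenceSeqs(anno))
  covered <- pil[pil$coverage >= 30, ]
  expect_equal(mean(covered$mismatch_frequency), 0.02, tolerance = 0.25)
  expect_equal(sum(pil$dropoff), 300L)
})

test_that("the mask threshold is inclusive at 0.1", {
  prof <- data.frame(contig = "ref", pos = 0:2, ref_base = "A",
                     coverage = c(100L, 100L, 0L), match = c(91L, 90L, 0L),
                     mismatch = c(9L, 10L, 0L), n_A = 0L, n_C = 0L,
                     n_G = 0L, n_T = 0L, n_del = 0L, dropoff = 0L,
                     mismatch_frequency = c(0.09, 0.10, NA))
  fl <- flagModifiedSites(prof, 0.1)
  expect_false(fl$flagged[1])                 # 0.09: masked
  expect_true(fl$flagged[2])                  # 0.10: retained
  expect_equal(fl$mask_reason[1], "below_threshold")
  expect_equal(fl$mask_reason[3], "no_coverage")
})

test_that("profile contrasts isolate a population-specific site", {
  anno <- fixture_annotation()
  hot <- data.frame(pos = 700L, rate = 0.4)
  processed <- simulateAlignmentSet(anno, 120, tailSpec("All-A", 20),
                                    error_rate = 0.02, seed = 51,
                                    hotspots = hot)
  precursor <- simulateAlignmentSet(anno, 120, tailSpec("All-A", 20),
                                    error_rate = 0.02, seed = 52)
  delta <- compareProfiles(processed$alignments, precursor$alignments,
                           referenceSeqs(anno))
  top <- delta$pos[which(delta$rank == 1)]
  cov_at <- function(sim, p) sum(sim$alignments$start <= p &
                                   sim$alignments$end > p)
  if (cov_at(processed, 700L) >= 20) expect_equal(top, 700L)
  # identical populations: all deltas vanish
  same <- compareProfiles(processed$alignments, processed$alignments,
                          referenceSeqs(anno))
  expect_true(all(abs(same$delta) < 1e-12, na.rm = TRUE))
  # swapping populations negates every delta
  swapped <- compareProfiles(precursor$alignments, processed$alignments,
                             referenceSeqs(anno))
  expect_equal(swapped$delta, -delta$delta)
  expect_error(compareProfiles(processed$alignments[0, ],
                               precursor$alignments,
                               referenceSeqs(anno)), "non-empty")
})

test_that("a 3x-background site is recovered as top outlier across seeds", {
  # dedicated small reference so every read covers the modified site
  set.seed(4)
  refseq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  tx <- data.frame(transcript_id = "rrna.t1", gene_id = "rrna",
                   biotype = "rRNA", contig = "rrna_ref", strand = "+",
                   three_prime_end = 380L, tx_start = 30L, tx_end = 380L)
  ex <- GenomicRanges::GRanges("rrna_ref", IRanges::IRanges(31, 380),
                               strand = "+", transcript_id = "rrna.t1",
                               gene_id = "rrna")
  anno1 <- new("TranscriptomeAnnotation", transcripts = tx, exons = ex,
               reference = Biostrings::DNAStringSet(c(rrna_ref = refseq)))
  base_rate <- 0.15
  hot <- data.frame(pos = 250L, rate = 3 * base_rate)
  hits <- vapply(1:100, function(s) {
    a <- simulateAlignmentSet(anno1, 100, tailSpec("All-A", 10),
                              error_rate = base_rate, seed = 1000 + s,
                              aligned_span = c(150L, 200L), hotspots = hot)
    b <- simulateAlignmentSet(anno1, 100, tailSpec("All-A", 10),
                              error_rate = base_rate, seed = 2000 + s,
                              aligned_span = c(150L, 200L))
    d <- compareProfiles(a$alignments, b$alignments, referenceSeqs(anno1),
                         mask_threshold = 0.1, min_coverage = 100L)
    isTRUE(d$pos[which(d$rank == 1)] == 250L)
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})
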