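ann <- fixture_annotation()

# hand-built alignment row whose RNA 3' end sits at `coord` for a "+" gene
aln_at <- function(coord, contig = "chrS", strand = "-", id = "r1") {
  data.frame(read_id = id, contig = contig, strand = strand,
             start = coord - 100L, end = coord, clip_tail = 10L,
             clip_other = 0L, clip_tail_seq = strrep("T", 10),
             aligned_seq = strrep("A", 100), mapped = TRUE,
             stringsAsFactors = FALSE)
}

test_that("the exon-end filter keeps exactly the +/- window", {
  tx <- transcripts(ann)
  tpe <- tx$three_prime_end[tx$strand == "+"][1]
  reads <- do.call(rbind, lapply(-20:20, function(o)
    aln_at(tpe + o, id = sprintf("off%+d", o))))
  kept <- filterCompleteReads(reads, ann, window = 10)
  offs <- as.integer(sub("off", "", kept$read_id))
  expect_setequal(offs, -10:10)
  rej <- attr(kept, "rejects")
  expect_equal(nrow(rej), 20L)
  expect_true(all(rej$reason == "no_exon_end_within_window"))
  # a read ending deep inside the exon, away from every isoform end, is an
  # internal degradation product
  inside <- aln_at(tpe - 30L, id = "internal")
  expect_equal(nrow(filterCompleteReads(inside, ann, 10)), 0L)
})

test_that("unknown contigs and empty annotation drop reads with reasons", {
  r <- aln_at(1000L, contig = "chrZ")
  expect_warning(kept <- filterCompleteReads(r, ann, 10), "absent")
  expect_equal(nrow(kept), 0L)
  expect_equal(attr(kept, "rejects")$reason, "unknown_contig")
  empty <- new("TranscriptomeAnnotation",
               transcripts = transcripts(ann)[0, ],
               exons = exons(ann)[0],
               reference = referenceSeqs(ann))
  kept2 <- filterCompleteReads(aln_at(1000L), empty, 10)
  expect_equal(nrow(kept2), 0L)
  expect_equal(attr(kept2, "rejects")$reason, "empty_annotation")
})

test_that("isoform assignment is inclusive at the window edge and tie-aware", {
  tx <- transcripts(ann)
  cand <- tx[tx$gene_id == tx$gene_id[1], ]
  tpe <- cand$three_prime_end[1]
  a10 <- assignToIsoform(aln_at(tpe + 10L), cand, 10)
  expect_equal(a10$status, "assigned")
  expect_equal(a10$distance, 10L)
  a11 <- assignToIsoform(aln_at(tpe + 11L), cand, 10)
  expect_equal(a11$status, "unassigned")
  # two candidates at the same distance: ambiguous
  two <- data.frame(transcript_id = c("tA", "tB"), gene_id = "g",
                    biotype = "pc", contig = "chrS", strand = "+",
                    three_prime_end = c(tpe - 4L, tpe + 4L),
                    stringsAsFactors = FALSE)
  amb <- assignToIsoform(aln_at(tpe), two, 10)
  expect_equal(amb$status, "ambiguous")
})

test_that("strand orientation decides which annotated end a read matches", {
  tx <- transcripts(ann)
  plus <- tx[tx$strand == "+", ][1, ]
  minus <- tx[tx$strand == "-", ][1, ]
  # a reverse-orientation alignment ending at the + transcript end: assigned
  r <- aln_at(plus$three_prime_end, strand = "-")
  expect_equal(assignToIsoform(r, tx, 10)$transcript_id,
               plus$transcript_id)
  # flipping the record's strand makes it a forward alignment whose 3' end
  # is its start; at the - transcript end it matches the - isoform instead
  r2 <- r
  r2$strand <- "+"
  r2$start <- minus$three_prime_end
  r2$end <- r2$start + 100L
  expect_equal(assignToIsoform(r2, tx, 10)$transcript_id,
               minus$transcript_id)
})

test_that("assignment conserves counts across status classes", {
  sim <- simulateAlignmentSet(ann, 150, tailSpec("All-A", 30),
                              error_rate = 0, seed = 23, offsets = -15:15)
  ass <- assignReads(sim$alignments, ann, 10)
  expect_equal(nrow(ass), 150L)
  expect_equal(sum(table(ass$status)), 150L)
  expect_true(all(abs(ass$distance[ass$status == "assigned"]) <= 10))
})

test_that("RPM follows its definition and sums to one million", {
  ass <- data.frame(read_id = sprintf("r%d", 1:100),
                    transcript_id = "t", gene_id = rep(c("g1", "g2"),
                                                       c(5, 95)),
                    distance = 0L, window = 10L, status = "assigned",
                    stringsAsFactors = FALSE)
  rpm <- quantifyRpm(ass, ann)
  expect_equal(rpm$rpm[rpm$gene_id == "g1"], 5 / 100 * 1e6)
  expect_equal(sum(rpm$rpm), 1e6)
  one <- quantifyRpm(ass[ass$gene_id == "g2", ], ann)
  expect_equal(one$rpm, 1e6)
  none <- ass[0, ]
  expect_error(quantifyRpm(none, ann), "zero assigned")
})

test_that("replicate libraries from one abundance truth correlate in log-RPM", {
  tx <- transcripts(ann)
  w <- setNames(2^seq(0, 4, length.out = nrow(tx)), tx$transcript_id)
  rpm_of <- function(seed) {
    sim <- simulateAlignmentSet(ann, 800, tailSpec("All-A", 30),
                                error_rate = 0, seed = seed,
                                transcript_weights = w)
    ass <- assignReads(sim$alignments, ann, 10)
    quantifyRpm(ass, ann)
  }
  r1 <- rpm_of(31L); r2 <- rpm_of(32L)
  m <- merge(r1, r2, by = "gene_id")
  expect_gte(cor(log10(m$rpm.x), log10(m$rpm.y)), 0.95)
})
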