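adapter <- libraryAdapters()[["end_adapter"]]

test_that("adapter trimming respects the identity threshold", {
  read <- paste0(adapter, strrep("T", 30), "GTAAATAGAC")
  res <- trimEndAdapter(read, adapter)
  expect_true(res$report$trimmed)
  expect_equal(res$report$trimmed_bases, nchar(adapter))
  expect_equal(res$report$adapter_identity, 100)
  expect_equal(res$read, paste0(strrep("T", 30), "GTAAATAGAC"))
  # no adapter at all: nothing removed
  res2 <- trimEndAdapter(paste0(strrep("T", 30), "GTAAATAGAC"), adapter)
  expect_false(res2$report$trimmed)
  expect_equal(res2$report$trimmed_bases, 0L)
  # adapter degraded to ~39% identity (19 leading bases replaced): below 50
  bad <- paste0(strrep("N", 0), chartr("CTGA", "GACT",
                                       substr(adapter, 1, 19)),
                substr(adapter, 20, 31))
  res3 <- trimEndAdapter(paste0(bad, strrep("T", 30)), adapter)
  expect_lt(res3$report$adapter_identity, 50)
  expect_false(res3$report$trimmed)
  # 16 intact trailing bases (~52% identity): trimmed
  half <- paste0(chartr("CTGA", "GACT", substr(adapter, 1, 15)),
                 substr(adapter, 16, 31))
  res4 <- trimEndAdapter(paste0(half, strrep("T", 30)), adapter)
  expect_gte(res4$report$adapter_identity, 50)
  expect_true(res4$report$trimmed)
  expect_error(trimEndAdapter("ACGT", "ACGTACG"), "shorter than 10")
  # extra_end_trim removes further bases inward
  res5 <- trimEndAdapter(read, adapter, extra_end_trim = 2)
  expect_equal(res5$report$trimmed_bases, nchar(adapter) + 2L)
})

test_that("tails are extracted from soft-clips in RNA sense", {
  # simulated record round-trip, error-free
  anno <- fixture_annotation()
  sim <- simulateAlignmentSet(anno, 20, tailSpec("Term-U", 20, n_mod = 1),
                              error_rate = 0, seed = 8)
  for (i in seq_len(5)) {
    tl <- extractTail(sim$alignments[i, ])
    expect_equal(tl$rna_sense_bases, sim$truth$tail_rna[i])
  }
  # printed pG5 design: cDNA tail CCCCC+25T -> RNA 25A then GGGGG
  reg <- standardsRegistry()
  pg5 <- reg[reg$name == "cDNA_p25A_pG5_standard_30", ]
  rec <- data.frame(read_id = "pg5", clip_tail_seq =
                      paste0(pg5$adapter_prefix, pg5$design_tail_composition),
                    stringsAsFactors = FALSE)
  tl <- extractTail(rec)
  expect_equal(tl$rna_sense_bases, paste0(strrep("A", 25), "GGGGG"))
  # zero-length clip -> no tail
  expect_null(extractTail(data.frame(read_id = "x", clip_tail_seq = "")))
  # missing soft-clip info -> malformed alignment
  expect_error(extractTail(data.frame(read_id = "x")), "malformed")
})

test_that("the A-content filter is strict at the threshold", {
  expect_true(filterAContent(strrep("A", 30)))
  expect_false(filterAContent(paste0(strrep("A", 24), strrep("G", 6))))  # 80.0%
  expect_true(filterAContent(paste0(strrep("A", 25), strrep("U", 5))))   # 83.3%
  expect_error(filterAContent(""), "empty tail")
})

test_that("classification matches the printed standards and stated rules", {
  reg <- standardsRegistry()
  expect_class <- function(name, cls) {
    rna <- reg$design_tail_rna[reg$name == name]
    expect_equal(as.character(classifyTail(rna)), cls, info = name)
  }
  expect_class("cDNA_pA_standard_30", "All-A")
  expect_class("cDNA_p29A_pU1_standard_30", "Term-U")
  expect_class("cDNA_p27A_pU3_standard_30", "Term-U")
  expect_class("cDNA_p25A_pU5_standard_30", "Term-U")
  expect_class("cDNA_p25A_pC5_standard_30", "Term-C")
  expect_class("cDNA_p25A_pG5_standard_30", "Term-G")
  expect_class("cDNA_pA_internalG_standard_30", "Int-G")
  # terminal precedence over internal
  expect_equal(as.character(classifyTail(paste0(strrep("A", 10), "G",
                                                strrep("A", 15), "UU"))),
               "Term-U")
  # internal tie broken toward the 3' end
  expect_equal(as.character(classifyTail("AAGAAAAUAAAA")), "Int-U")
  expect_equal(as.character(classifyTail("AAUAAAAGAAAA")), "Int-G")
  # tails shorter than the window are classified on their full length
  expect_equal(as.character(classifyTail("AAAAU", 30)), "Term-U")
  # only the last 30 nt are inspected
  long <- paste0("GGGGG", strrep("A", 40))
  expect_equal(as.character(classifyTail(long, 30)), "All-A")
})

test_that("classes partition every retained tail (10^4 random tails)", {
  set.seed(42)
  classes <- c("All-A", "Term-G", "Term-U", "Term-C", "Int-G", "Int-U",
               "Int-C")
  tails <- vapply(1:10000, function(i) {
    len <- sample(5:60, 1)
    n_bad <- rbinom(1, len, 0.05)
    tl <- rep("A", len)
    if (n_bad > 0)
      tl[sample(len, n_bad)] <- sample(c("C", "G", "U"), n_bad, TRUE)
    paste(tl, collapse = "")
  }, "")
  labels <- vapply(tails, function(x) as.character(classifyTail(x)), "")
  expect_false(anyNA(labels))
  expect_true(all(labels %in% classes))
  expect_equal(sum(table(factor(labels, levels = classes))), 10000L)
})

test_that("designed classes are recovered from simulated reads", {
  anno <- fixture_annotation()
  spec <- tailSpec(c("All-A", "Term-U", "Int-G"), c(40, 30, 50))
  sim0 <- simulateAlignmentSet(anno, 150, spec, error_rate = 0, seed = 13)
  t0 <- classifyTails(sim0$alignments)
  m0 <- merge(t0, sim0$truth, by = "read_id", suffixes = c("_obs", "_true"))
  expect_true(all(m0$kept))
  expect_equal(mean(m0$class_obs == m0$class_true), 1)
  # with 2% substitutions: terminal/internal designs stay recoverable;
  # the strict All-A bin degrades exactly as the error model predicts
  # (any substitution in the 30-nt window reclassifies the tail)
  sim2 <- simulateAlignmentSet(anno, 400, spec, error_rate = 0.02, seed = 14)
  t2 <- classifyTails(sim2$alignments)
  m2 <- merge(t2, sim2$truth, by = "read_id", suffixes = c("_obs", "_true"))
  m2 <- m2[m2$kept, ]
  rec <- tapply(m2$class_obs == m2$class_true, m2$class_true, mean)
  expect_gte(rec[["Term-U"]], 0.90)
  expect_gte(rec[["Int-G"]], 0.90)
  expect_equal(unname(rec[["All-A"]]), 0.98^30, tolerance = 0.12)
})

test_that("positional profiles are right-justified and normalized", {
  # error-free single-terminal-U tails: P(U) = 1 at -1, P(A) = 1 elsewhere
  tails <- rep(paste0(strrep("A", 29), "U"), 100)
  prof <- positionalProfile(tails, 20)
  expect_equal(prof$p_U[prof$position == -1], 1)
  expect_true(all(prof$p_A[prof$position <= -2] == 1))
  # a short tail covers only its own positions
  p1 <- positionalProfile("AAAU", 20)
  expect_true(all(p1$n[p1$position < -4] == 0))
  expect_true(all(is.na(p1$p_A[p1$position < -4])))
  # covered positions always sum to one
  set.seed(1)
  mix <- vapply(1:50, function(i)
    paste(sample(c("A", "G", "U"), sample(3:40, 1), TRUE,
                 prob = c(.8, .1, .1)), collapse = ""), "")
  pm <- positionalProfile(mix, 20)
  sums <- unname(rowSums(pm[pm$n > 0, c("p_A", "p_C", "p_G", "p_U")]))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  expect_error(positionalProfile(character()), "no tails")
})

test_that("designed non-A content stands far above a pure-A control", {
  anno <- fixture_annotation()
  ctrl <- simulateAlignmentSet(anno, 100, tailSpec("All-A", 30),
                               error_rate = 0.01, seed = 15)
  mod <- simulateAlignmentSet(anno, 100, tailSpec("Term-U", 30, n_mod = 5),
                              error_rate = 0.01, seed = 16)
  nonA <- function(sim) {
    t <- classifyTails(sim$alignments)
    p <- positionalProfile(t[t$kept, ], 20)
    mean(1 - p$p_A, na.rm = TRUE)
  }
  expect_gt(nonA(mod) / nonA(ctrl), 4)
})

test_that("classification commutes with extraction (orientation round-trip)", {
  anno <- fixture_annotation()
  sim <- simulateAlignmentSet(anno, 60,
                              tailSpec(c("Term-C", "Int-U"), c(35, 45)),
                              error_rate = 0.02, seed = 17)
  t <- classifyTails(sim$alignments)
  m <- merge(t, sim$truth, by = "read_id", suffixes = c("_obs", "_true"))
  # classifying the extracted tail string equals the stored class
  again <- vapply(m$tail_seq, function(x) as.character(classifyTail(x)), "")
  expect_equal(unname(again[m$kept]), m$class_obs[m$kept])
})
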