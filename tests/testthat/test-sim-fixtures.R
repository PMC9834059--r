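test_that("pore model tables are deterministic, seed-sensitive and complete", {
  pm1 <- makePoreModel(5, 7)
  pm2 <- makePoreModel(5, 7)
  expect_identical(poreLevels(pm1), poreLevels(pm2))
  expect_identical(poreSds(pm1), poreSds(pm2))
  pm3 <- makePoreModel(5, 8)
  expect_gt(sum(poreLevels(pm1) != poreLevels(pm3)), 0)
  expect_length(poreLevels(pm1), 4^5)
  expect_true(all(poreSds(pm1) > 0))
  expect_error(makePoreModel(3, 1), "must be 4, 5 or 6")
  # homopolymer k-mers distinct; polyT/polyA plateaus >= 2 sds from the rest
  homo <- vapply(c("A", "C", "G", "T"), function(b) strrep(b, 5), "")
  expect_false(anyDuplicated(poreLevels(pm1)[homo]) > 0)
  lev <- poreLevels(pm1)
  plateau <- grepl("^[TC]*$", names(lev)) & nchar(gsub("T", "", names(lev))) <= 1 |
             grepl("^[AG]*$", names(lev)) & nchar(gsub("A", "", names(lev))) <= 1
  generic <- lev[!plateau]
  tt <- lev[strrep("T", 5)]; aa <- lev[strrep("A", 5)]
  max_sd <- max(poreSds(pm1))
  expect_true(all(abs(generic - tt) >= 2 * max_sd))
  expect_true(all(abs(generic - aa) >= 2 * max_sd))
})

test_that("standards registry matches the printed designs", {
  reg <- standardsRegistry()
  expect_equal(nrow(reg), 12L)
  lens <- reg$design_tail_length[reg$series == "length_series"]
  expect_equal(sort(lens), c(0L, 15L, 30L, 60L, 90L, 120L))
  expect_equal(reg$design_tail_length[reg$name == "cDNA_pA_standard_0"], 0L)
  expect_true(startsWith(
    reg$design_tail_composition[reg$name == "cDNA_p25A_pG5_standard_30"],
    "CCCCC"))
  expect_true(all(startsWith(reg$full_sequence, reg$adapter_prefix)))
  # tail is the substring between adapter and insert
  alen <- nchar(reg$adapter_prefix[1])
  expect_equal(substr(reg$full_sequence, alen + 1,
                      alen + reg$design_tail_length),
               reg$design_tail_composition)
  # the composition designs in RNA sense: pU1 ends with a single U
  pu1 <- reg[reg$name == "cDNA_p29A_pU1_standard_30", ]
  expect_equal(pu1$design_tail_composition, paste0("A", strrep("T", 29)))
  expect_equal(pu1$design_tail_rna, paste0(strrep("A", 29), "U"))
})

test_that("tail regions are recovered from every printed standard", {
  reg <- standardsRegistry()
  for (i in seq_len(nrow(reg))) {
    tr <- detectTailRegion(reg$full_sequence[i])
    if (reg$design_tail_length[i] == 0L) {
      expect_null(tr)
    } else {
      expect_equal(tr[1], 31L)
      expect_equal(tr[2] - tr[1], reg$design_tail_length[i],
                   info = reg$name[i])
    }
  }
})

test_that("squiggle simulation is reproducible with consistent truth spans", {
  pm <- fixture_pore()
  reg <- standardsRegistry()
  s1 <- simulateSquiggle(reg$full_sequence[3], pm, seed = 11)
  s2 <- simulateSquiggle(reg$full_sequence[3], pm, seed = 11)
  expect_identical(signalSamples(s1$squiggle), signalSamples(s2$squiggle))
  s3 <- simulateSquiggle(reg$full_sequence[3], pm, seed = 12)
  expect_false(identical(signalSamples(s1$squiggle),
                         signalSamples(s3$squiggle)))
  # tail-free standard: zero-length tail span
  s0 <- simulateSquiggle(reg$full_sequence[1], pm, seed = 4)
  expect_equal(s0$truth$true_tail_nt, 0L)
  expect_equal(s0$truth$tail_end, s0$truth$tail_start)
  # noiseless standard_60: span is the realized dwell sum, expectation 600
  spans <- vapply(1:30, function(i) {
    s <- simulateSquiggle(reg$full_sequence[4], pm, dwell_mean = 10,
                          noise_sd = 0, seed = 100 + i)
    s$truth$tail_end - s$truth$tail_start
  }, 0)
  expect_gt(mean(spans), 600 * 0.9)
  expect_lt(mean(spans), 600 * 1.1)
  # spans are disjoint and inside the signal
  s <- simulateSquiggle(reg$full_sequence[4], pm, seed = 5)
  tr <- s$truth
  expect_lte(tr$adapter_end, tr$tail_start)
  expect_lte(tr$tail_end, sampleCount(s$squiggle))
  expect_error(simulateSquiggle("", pm), "non-empty")
})

test_that("alignment simulation honours tails, errors and offsets", {
  anno <- fixture_annotation()
  sim <- simulateAlignmentSet(anno, 100, tailSpec("All-A", 30),
                              error_rate = 0, seed = 5)
  expect_equal(nrow(sim$alignments), 100L)
  # error-free: extracted clip tail equals the designed truth tail
  tails <- classifyTails(sim$alignments)
  m <- merge(tails, sim$truth, by = "read_id")
  expect_true(all(m$tail_seq == m$tail_rna))
  # Term-U(3): every RNA-sense truth tail ends UUU
  simU <- simulateAlignmentSet(anno, 50, tailSpec("Term-U", 30, n_mod = 3),
                               error_rate = 0, seed = 6)
  expect_true(all(endsWith(simU$truth$tail_rna, "UUU")))
  # uniform offsets in [-20, 20]: P(|offset| <= 10) = 21/41 exactly
  simO <- simulateAlignmentSet(anno, 4000, tailSpec("All-A", 30),
                               error_rate = 0, seed = 9, offsets = -20:20)
  frac <- mean(abs(simO$truth$offset) <= 10)
  expect_lt(abs(frac - 21 / 41), 0.03)
  expect_error(simulateAlignmentSet(anno, 0), "must be > 0")
  expect_error(simulateAlignmentSet(anno, 10, error_rate = 0.5), "error_rate")
})
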