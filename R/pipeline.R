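# Run configuration and end-to-end pipeline.

#' Build a validated run configuration
#'
#' Collects every tunable threshold of the pipeline with its default, checks
#' domains, and fingerprints the result so outputs can be traced to the
#' configuration that produced them.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param window isoform / exon-end window in nt, inclusive (default 10).
#' @param a_content_threshold strict A-content percent filter (default 80).
#' @param last_n_class classification window, nt (default 30).
#' @param last_n_profile positional profile window, nt (default 20).
#' @param min_reads strict per-unit coverage filter (default 10).
#' @param mask_threshold mismatch-frequency mask (default 0.1).
#' @param end_threshold adapter trimming identity percent (default 50).
#' @param extra_end_trim extra bases trimmed after the adapter (default 0).
#' @param alpha significance level (default 0.05).
#' @param n_reads simulated alignment reads (default 300).
#' @param n_per_standard simulated squiggles per cDNA standard (default 20).
#' @param dwell_mean,noise_sd squiggle simulation parameters.
#' @param error_rate simulated per-base substitution rate (default 0.02).
#' @return list of class \code{tailcap_config} with a \code{hash} element.
#' @export
runConfig <- function(out_dir = tempfile("tailcap_run_"), seed = 1L,
                      window = 10L, a_content_threshold = 80,
                      last_n_class = 30L, last_n_profile = 20L,
                      min_reads = 10L, mask_threshold = 0.1,
                      end_threshold = 50, extra_end_trim = 0L,
                      alpha = 0.05, n_reads = 300L, n_per_standard = 20L,
                      dwell_mean = 10, noise_sd = 0.3, error_rate = 0.02) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              window = as.integer(window),
              a_content_threshold = a_content_threshold,
              last_n_class = as.integer(last_n_class),
              last_n_profile = as.integer(last_n_profile),
              min_reads = as.integer(min_reads),
              mask_threshold = mask_threshold,
              end_threshold = end_threshold,
              extra_end_trim = as.integer(extra_end_trim),
              alpha = alpha, n_reads = as.integer(n_reads),
              n_per_standard = as.integer(n_per_standard),
              dwell_mean = dwell_mean, noise_sd = noise_sd,
              error_rate = error_rate)
  stopifnot(cfg$window >= 0, cfg$a_content_threshold >= 0,
            cfg$a_content_threshold <= 100, cfg$last_n_class > 0,
            cfg$last_n_profile > 0, cfg$min_reads >= 0,
            cfg$mask_threshold >= 0, cfg$mask_threshold <= 1,
            cfg$end_threshold >= 0, cfg$end_threshold <= 100,
            cfg$extra_end_trim >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_reads > 0, cfg$n_per_standard > 0, cfg$dwell_mean >= 3,
            cfg$noise_sd >= 0, cfg$error_rate >= 0, cfg$error_rate < 0.2)
  # fingerprint the analysis parameters; the output path is not part of
  # what determines the results
  fp <- cfg[setdiff(names(cfg), "out_dir")]
  cfg$hash <- contentHash(jsonlite::toJSON(fp[order(names(fp))],
                                           auto_unbox = TRUE, digits = NA))
  class(cfg) <- "tailcap_config"
  cfg
}

#' Serialize / restore a run configuration
#'
#' @param config a \code{tailcap_config}.
#' @param path JSON file.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$hash <- NULL
  do.call(runConfig, raw)
}

#' Run the full pipeline on simulated fixtures
#'
#' Stages: \code{simulate} (squiggles for every cDNA standard, a synthetic
#' transcriptome with soft-clipped alignments, written as signal container /
#' FASTQ / SAM / GTF / BED / truth TSVs), \code{taillen} (signal-level tail
#' length table), \code{tailcomp} (tail extraction, classification and
#' positional profile), \code{assign} (3'-end filtering, isoform assignment,
#' RPM table), \code{stats} (across-isoform tail divergence scan) and
#' \code{modprofile} (per-site mismatch/drop-off contrast between the two
#' busiest isoform populations). Every output carries the configuration
#' hash; per-read rejections go to a rejects file, not stdout.
#'
#' @param config a \code{tailcap_config} from \code{\link{runConfig}}.
#' @param steps subset of stages to run (default all, in order).
#' @return (invisibly) the output directory; a \code{summary.json} file
#'   summarises the run.
#' @export
runPipeline <- function(config = runConfig(),
                        steps = c("simulate", "taillen", "tailcomp",
                                  "assign", "stats", "modprofile")) {
  stopifnot(inherits(config, "tailcap_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  meta <- c(config_hash = config$hash)
  writeRunConfig(config, file.path(out, "config.json"))
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  summary <- list(config_hash = config$hash)

  if ("simulate" %in% steps) {
    pore <- makePoreModel(5L, seed = config$seed)
    reg <- standardsRegistry()
    sims <- list(); truths <- list()
    for (i in seq_len(nrow(reg))) {
      s <- simulateSquiggleSet(reg$full_sequence[i], pore,
                               n = config$n_per_standard,
                               dwell_mean = config$dwell_mean,
                               noise_sd = config$noise_sd,
                               seed = config$seed + 1000L * i,
                               id_prefix = reg$name[i])
      sims <- c(sims, s$squiggles)
      truths[[i]] <- s$truth
    }
    writeSignalContainer(sims, file.path(out, "signals.tsv"))
    writeTsv(do.call(rbind, truths), file.path(out, "signal_truth.tsv"), meta)
    anno <- makeTestTranscriptome(seed = config$seed)
    sim <- simulateAlignmentSet(
      anno, config$n_reads,
      tail_spec = tailSpec(c("All-A", "Term-U", "Int-G"),
                           lengths = c(40L, 30L, 50L), probs = c(.6, .2, .2)),
      error_rate = config$error_rate, seed = config$seed + 17L,
      offsets = -15:15)
    writeAlignmentsSAM(sim$alignments, file.path(out, "reads.sam"),
                       stats::setNames(Biostrings::width(anno@reference),
                                       names(anno@reference)))
    writeReadsFastq(readSequencesFromAlignments(sim$alignments),
                    file.path(out, "reads.fastq"))
    writeAnnotationGTF(anno, file.path(out, "annotation.gtf"))
    writeThreePrimeEndsBED(anno, file.path(out, "three_prime_ends.bed"))
    writeTsv(sim$truth, file.path(out, "alignment_truth.tsv"), meta)
    Biostrings::writeXStringSet(anno@reference,
                                file.path(out, "reference.fasta"))
    summary$n_squiggles <- length(sims)
    summary$n_alignments <- nrow(sim$alignments)
    logline("simulate: %d squiggles, %d alignments", length(sims),
            nrow(sim$alignments))
  }

  if ("taillen" %in% steps) {
    sq <- readSignalContainer(file.path(out, "signals.tsv"))
    tl <- estimateTailLengths(sq)
    writeTsv(tl, file.path(out, "tail_lengths.tsv"), meta)
    summary$n_tail_calls <- nrow(tl)
    logline("taillen: %d calls", nrow(tl))
  }

  if ("tailcomp" %in% steps) {
    aln <- readAlignmentsSAM(file.path(out, "reads.sam"))
    tails <- classifyTails(aln, end_threshold = config$end_threshold,
                           extra_end_trim = config$extra_end_trim,
                           a_threshold = config$a_content_threshold,
                           last_n = config$last_n_class)
    writeTsv(tails, file.path(out, "tail_classes.tsv"), meta)
    kept <- tails[tails$kept, , drop = FALSE]
    if (nrow(kept)) {
      prof <- positionalProfile(kept, config$last_n_profile)
      writeTsv(prof, file.path(out, "tail_profile.tsv"), meta)
    }
    summary$n_tails_kept <- sum(tails$kept)
    logline("tailcomp: %d tails, %d kept", nrow(tails), sum(tails$kept))
  }

  if ("assign" %in% steps) {
    aln <- readAlignmentsSAM(file.path(out, "reads.sam"))
    anno <- readAnnotationGTF(
      file.path(out, "annotation.gtf"),
      Biostrings::readDNAStringSet(file.path(out, "reference.fasta")))
    names(anno@reference) <- sub(" .*", "", names(anno@reference))
    complete <- filterCompleteReads(aln, anno, config$window)
    rejects <- attr(complete, "rejects")
    writeTsv(rejects, file.path(out, "rejects.tsv"), meta)
    ass <- assignReads(complete, anno, config$window)
    writeTsv(ass, file.path(out, "assignments.tsv"), meta)
    rpm <- quantifyRpm(ass, anno)
    writeTsv(rpm, file.path(out, "expression_rpm.tsv"), meta)
    summary$n_complete <- nrow(complete)
    summary$n_assigned <- sum(ass$status == "assigned")
    logline("assign: %d complete, %d assigned", nrow(complete),
            sum(ass$status == "assigned"))
  }

  if ("stats" %in% steps) {
    tails <- readTsv(file.path(out, "tail_classes.tsv"))
    ass <- readTsv(file.path(out, "assignments.tsv"))
    tab <- merge(ass[ass$status == "assigned",
                     c("read_id", "transcript_id", "gene_id")],
                 data.frame(read_id = tails$read_id,
                            tail_length_nt = nchar(tails$tail_seq)),
                 by = "read_id")
    scan <- divergenceScan(tab, unit = "gene_id", grouping = "transcript_id",
                           min_reads = config$min_reads,
                           alpha = config$alpha)
    if (!is.null(scan$comparisons))
      writeTsv(scan$comparisons, file.path(out, "tail_divergence.tsv"), meta)
    summary$divergence <- list(
      n_tested = scan$n_tested,
      fraction_significant_raw = scan$fraction_significant_raw,
      fraction_significant_adjusted = scan$fraction_significant_adjusted)
    logline("stats: %d units tested", scan$n_tested)
  }

  if ("modprofile" %in% steps) {
    aln <- readAlignmentsSAM(file.path(out, "reads.sam"))
    ass <- readTsv(file.path(out, "assignments.tsv"))
    ref <- Biostrings::readDNAStringSet(file.path(out, "reference.fasta"))
    names(ref) <- sub(" .*", "", names(ref))
    ok <- ass$status == "assigned"
    top <- names(sort(table(ass$transcript_id[ok]), decreasing = TRUE))
    if (length(top) >= 2L) {
      popA <- aln[aln$read_id %in% ass$read_id[ok & ass$transcript_id == top[1]], ]
      popB <- aln[aln$read_id %in% ass$read_id[ok & ass$transcript_id == top[2]], ]
      pil <- flagModifiedSites(buildPileup(rbind(popA, popB), ref),
                               config$mask_threshold)
      writeTsv(pil[pil$coverage > 0, ], file.path(out, "site_profile.tsv"),
               meta)
      delta <- compareProfiles(popA, popB, ref,
                               mask_threshold = config$mask_threshold)
      writeTsv(delta, file.path(out, "profile_delta.tsv"), meta)
      summary$n_sites_flagged <- sum(pil$flagged, na.rm = TRUE)
      logline("modprofile: %d flagged sites", summary$n_sites_flagged)
    }
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
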