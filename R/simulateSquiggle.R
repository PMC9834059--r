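# Squiggle simulation with known ground truth.

#' Simulate a raw-signal read from a cDNA sequence
#'
#' Emits an adapter-stub segment (a fixed number of samples at a level
#' outside the k-mer level range, standing in for the sequencing adapter
#' that precedes the first base-called base) followed by one event per base:
#' the level of the k-mer starting at that base, held for a dwell drawn from
#' a shifted geometric distribution (minimum 3 samples, mean
#' \code{dwell_mean}), with Gaussian noise of sd \code{noise_sd} added to
#' every sample. The ground-truth record gives the half-open sample spans of
#' the end-adapter bases and of the tail region located with
#' \code{\link{detectTailRegion}} (or supplied explicitly).
#'
#' @param cdna_sequence cDNA-sense base string (adapter + tail + insert).
#' @param pore a \linkS4class{PoreModel}.
#' @param dwell_mean mean samples per nucleotide (>= 3).
#' @param noise_sd sd of the additive Gaussian current noise (>= 0).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param read_id identifier for the simulated read.
#' @param tail_region optional 0-based half-open base interval of the tail
#'   within \code{cdna_sequence}; default: detected from the sequence.
#' @param sampling_rate nominal sampling rate recorded as metadata.
#' @return list with elements \code{squiggle} (a \linkS4class{Squiggle}) and
#'   \code{truth} (one-row data.frame: read_id, true_tail_nt, tail_start,
#'   tail_end, adapter_start, adapter_end -- 0-based half-open sample
#'   spans -- dwell_mean, seed).
#' @export
#' @examples
#' pm <- makePoreModel(5, 7)
#' std <- standardsRegistry()
#' sim <- simulateSquiggle(std$full_sequence[3], pm, seed = 1)
#' sim$truth$true_tail_nt  # 30
simulateSquiggle <- function(cdna_sequence, pore, dwell_mean = 10,
                             noise_sd = 0.3, seed = 1L, read_id = "read_1",
                             tail_region = NULL, sampling_rate = 4000) {
  if (!is.character(cdna_sequence) || length(cdna_sequence) != 1L ||
      nchar(cdna_sequence) == 0)
    stop("'cdna_sequence' must be a non-empty base string")
  if (!methods::is(pore, "PoreModel")) stop("'pore' must be a PoreModel")
  if (dwell_mean < 3) stop("'dwell_mean' must be >= 3")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  k <- pore@k
  n <- nchar(cdna_sequence)
  if (is.null(tail_region)) tail_region <- detectTailRegion(cdna_sequence)
  withSeed(seed, {
    npos <- max(n - k + 1L, 1L)
    b <- seq_len(n)
    # one event per base: k-mer starting at the base, switching to the
    # k-mer ending at it for the last k-1 bases (keeps end events distinct)
    starts <- ifelse(b <= npos, b, pmax(b - k + 1L, 1L))
    km <- substring(cdna_sequence, starts, starts + k - 1L)
    levels <- unname(pore@levels[km])
    if (anyNA(levels))
      stop("sequence contains bases outside the A/C/G/T alphabet")
    dwell <- if (dwell_mean == 3) rep(3L, n) else
      3L + stats::rgeom(n, 1 / (dwell_mean - 2))
    # truncate the heavy geometric tail: a single base never dwells longer
    # than 6x the mean, keeping event durations within the plausible range
    dwell <- pmin(dwell, as.integer(ceiling(6 * dwell_mean)))
    sig <- c(rep(.STUB_LEVEL, .STUB_SAMPLES), rep(levels, dwell))
    if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
    cum <- c(0L, cumsum(dwell)) + .STUB_SAMPLES  # samples before base i+1
    alen <- nchar(libraryAdapters()[["end_adapter"]])
    alen <- min(alen, n)
    if (is.null(tail_region)) {
      tnt <- 0L; tspan <- c(cum[alen + 1L], cum[alen + 1L])
    } else {
      tnt <- tail_region[2] - tail_region[1]
      tspan <- c(cum[tail_region[1] + 1L], cum[tail_region[2] + 1L])
    }
    squiggle <- methods::new("Squiggle", read_id = read_id,
                             samples = sig, sampling_rate = sampling_rate,
                             basecalled_length = n)
    truth <- data.frame(
      read_id = read_id, true_tail_nt = as.integer(tnt),
      tail_start = as.integer(tspan[1]), tail_end = as.integer(tspan[2]),
      adapter_start = .STUB_SAMPLES, adapter_end = as.integer(cum[alen + 1L]),
      dwell_mean = dwell_mean, seed = as.integer(seed),
      stringsAsFactors = FALSE)
    list(squiggle = squiggle, truth = truth)
  })
}

#' Simulate a batch of squiggles from one sequence
#'
#' Convenience wrapper calling \code{\link{simulateSquiggle}} n times with
#' per-read seeds derived from \code{seed}.
#'
#' @inheritParams simulateSquiggle
#' @param n number of reads.
#' @return list with \code{squiggles} (list of Squiggle) and \code{truth}
#'   (data.frame, one row per read).
#' @export
simulateSquiggleSet <- function(cdna_sequence, pore, n, dwell_mean = 10,
                                noise_sd = 0.3, seed = 1L,
                                id_prefix = "read") {
  sims <- lapply(seq_len(n), function(i)
    simulateSquiggle(cdna_sequence, pore, dwell_mean, noise_sd,
                     seed = seed + i - 1L,
                     read_id = sprintf("%s_%04d", id_prefix, i)))
  list(squiggles = lapply(sims, `[[`, "squiggle"),
       truth = do.call(rbind, lapply(sims, `[[`, "truth")))
}
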