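# Signal-level polyA tail length estimation.
#
# Principle: the tail of a template-switched cDNA read traverses the pore as
# a long homopolymer, producing a low-variance stretch of current directly
# after the end adapter. Its duration, divided by the read's translocation
# rate (samples per nucleotide, estimated from the non-tail part of the
# read: non-tail duration over non-tail base count), gives the tail length
# in nucleotides. This is the duration-ratio principle: the tail duration is
# compared with the duration of the rest of the sequenced read rather than
# converted through any fixed translocation constant.

#' Default tail segmentation parameters
#'
#' \describe{
#'   \item{smooth_window}{moving-mean window (samples) applied to the
#'     normalized signal before segmentation; light denoising that keeps
#'     per-base plateaus visible. Default 5.}
#'   \item{var_window}{rolling-variance window (samples). Default 25.}
#'   \item{noise_factor}{the variance threshold is
#'     \code{noise_factor * (smoothed noise floor)}, where the noise floor is
#'     estimated robustly from the median squared first difference of the
#'     normalized signal. Adaptive thresholding keeps the calling behaviour
#'     stable whether the tail occupies 0% or 60% of the read, which a fixed
#'     threshold in normalized units cannot do. Default 32.}
#'   \item{var_floor}{lower bound on the variance threshold, for noiseless
#'     signals. Default 1e-5.}
#'   \item{min_segment_samples}{minimal below-threshold run length (before
#'     window-support correction) for a segment call; rejects spurious flat
#'     stretches from single-event dwell outliers. Default 60.}
#'   \item{max_gap_samples}{below-threshold runs separated by at most this
#'     many samples are merged, tolerating brief interruptions inside the
#'     tail. Default 20.}
#'   \item{adapter_boundary_hint}{optional known 0-based sample index of the
#'     adapter-stub boundary; NULL to detect it as the largest level
#'     change-point in the first quarter of the read.}
#'   \item{rate_bounds}{plausible translocation rates (samples/nt); calls
#'     with a rate outside this range are flagged unreliable. Default
#'     c(3, 40).}
#'   \item{context_correction_nt}{additive correction (nt) for the k-mer
#'     context at the segment boundaries: with the fixed adapter suffix of
#'     the library chemistry (ending ...TTC) the homopolymer plateau of an
#'     L-nt tail spans L - 1 base events, so one nucleotide is added back.
#'     Default 1.}
#' }
#'
#' @return named list of defaults, possibly overridden.
#' @param ... name = value overrides of individual parameters.
#' @export
tailParams <- function(...) {
  p <- list(smooth_window = 5L, var_window = 25L, noise_factor = 32,
            var_floor = 1e-5, min_segment_samples = 60L,
            max_gap_samples = 20L, adapter_boundary_hint = NULL,
            rate_bounds = c(3, 40), context_correction_nt = 1)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown tail parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Robustly normalize a raw signal
#'
#' Centers on the median and scales by 1.4826 * MAD (falling back to the
#' standard deviation when the MAD is zero), preserving sample order.
#'
#' @param squiggle a \linkS4class{Squiggle} with at least 100 samples.
#' @return a \linkS4class{NormalizedSignal}.
#' @export
normalizeSignal <- function(squiggle) {
  if (!methods::is(squiggle, "Squiggle")) stop("'squiggle' must be a Squiggle")
  x <- squiggle@samples
  if (length(x) < 100L)
    stop("too-short read: need >= 100 samples, got ", length(x))
  center <- stats::median(x)
  scale <- 1.4826 * stats::mad(x, constant = 1)
  if (scale == 0) scale <- stats::sd(x)
  if (is.na(scale) || scale == 0)
    stop("degenerate signal: zero spread, cannot normalize")
  methods::new("NormalizedSignal", read_id = squiggle@read_id,
               z = (x - center) / scale, center = center, scale = scale)
}

# largest change-point of the smoothed signal within the first quarter,
# located with a lagged difference; returns a 0-based sample index
.detectBoundary <- function(zs, lag = 25L) {
  q <- max(floor(length(zs) / 4), lag + 2L)
  q <- min(q, length(zs))
  d <- abs(zs[(lag + 1L):q] - zs[1:(q - lag)])
  which.max(d) + lag %/% 2L  # center of the lag window, ~0-based in z coords
}

#' Locate the tail segment of a normalized signal
#'
#' Smooths the normalized signal with a moving mean, then scans the rolling
#' variance after the detected adapter boundary (the largest level
#' change-point in the first quarter of the read, or
#' \code{adapter_boundary_hint}). Below-threshold runs are merged across
#' gaps of at most \code{max_gap_samples}; the first merged run of at least
#' \code{min_segment_samples} is returned, its boundaries widened to the
#' full support of the rolling windows. The variance threshold adapts to the
#' read's noise floor (see \code{\link{tailParams}}). Absence of a tail is a
#' value (NULL), not an error.
#'
#' @param norm a \linkS4class{NormalizedSignal}.
#' @param params parameter list from \code{\link{tailParams}}.
#' @return a \linkS4class{TailSegment}, or NULL when no qualifying
#'   low-variance run exists.
#' @export
segmentTail <- function(norm, params = tailParams()) {
  if (!methods::is(norm, "NormalizedSignal"))
    stop("'norm' must be a NormalizedSignal")
  z <- norm@z
  sw <- params$smooth_window
  vw <- params$var_window
  if (length(z) < sw + vw + 4L) return(NULL)
  zs <- rollMean(z, sw)
  boundary <- params$adapter_boundary_hint %||% .detectBoundary(zs)
  noise_var <- stats::median(diff(z)^2) / 2
  thr <- max(params$noise_factor * noise_var / sw, params$var_floor)
  v <- rollVar(zs, vw)
  mask <- v < thr
  mask[seq_len(min(boundary, length(mask)))] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(NULL)
  if (nrow(runs) > 1L) {  # merge runs across short gaps
    merged <- list(runs[1L, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, "start"] - last["end"] - 1L <= params$max_gap_samples)
        merged[[length(merged)]]["end"] <- runs[i, "end"]
      else merged[[length(merged) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, merged)
  }
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >=
                 params$min_segment_samples, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  seg <- runs[1L, ]  # nearest the adapter boundary: tails are adapter-adjacent
  # v[i] summarises z[i .. i + vw + sw - 2]; expand to full window support
  start <- as.integer(seg[["start"]] - 1L)            # 0-based
  end <- as.integer(seg[["end"]] + vw + sw - 2L)      # half-open
  end <- min(end, length(z))
  zseg <- z[(start + 1L):end]
  methods::new("TailSegment", start = start, end = end,
               mean_level = mean(zseg), variance = stats::var(zseg),
               boundary = as.integer(boundary))
}

#' Convert a tail segment duration to a tail length in nucleotides
#'
#' Estimates the per-read translocation rate from the non-tail, non-stub
#' part of the signal and the base-called read length, with one refinement
#' iteration: a provisional tail base count (from the whole-read rate) is
#' subtracted from the base-called length so that the final rate uses
#' non-tail bases over non-tail samples. The tail length is the tail
#' duration divided by this rate, plus a fixed k-mer context correction
#' (see \code{\link{tailParams}}). A NULL segment yields a zero_tail call;
#' a rate outside \code{rate_bounds} yields status "unreliable".
#'
#' @param squiggle the \linkS4class{Squiggle} the segment came from; its
#'   \code{basecalled_length} must be > 0.
#' @param segment a \linkS4class{TailSegment} or NULL.
#' @param params parameter list from \code{\link{tailParams}}.
#' @return a \linkS4class{TailCall}.
#' @export
callTailLength <- function(squiggle, segment, params = tailParams()) {
  if (!methods::is(squiggle, "Squiggle")) stop("'squiggle' must be a Squiggle")
  nb <- squiggle@basecalled_length
  if (nb <= 0L) stop("invalid input: basecalled_length must be > 0")
  if (is.null(segment))
    return(methods::new("TailCall", read_id = squiggle@read_id,
                        tail_samples = 0L, rate = NA_real_,
                        tail_length_nt = 0, status = "zero_tail"))
  n <- length(squiggle@samples)
  ts <- segment@end - segment@start
  boundary <- segment@boundary
  post_stub <- n - boundary         # samples carrying base-called bases
  rate0 <- post_stub / nb
  prov_nt <- ts / rate0
  denom_nt <- nb - prov_nt
  denom_samples <- post_stub - ts
  if (denom_nt <= 0 || denom_samples <= 0)
    return(methods::new("TailCall", read_id = squiggle@read_id,
                        tail_samples = as.integer(ts), rate = NA_real_,
                        tail_length_nt = 0, status = "unreliable"))
  rate <- denom_samples / denom_nt
  nt <- max(ts / rate + params$context_correction_nt, 0)
  status <- if (rate < params$rate_bounds[1] || rate > params$rate_bounds[2])
    "unreliable" else "called"
  methods::new("TailCall", read_id = squiggle@read_id,
               tail_samples = as.integer(ts), rate = rate,
               tail_length_nt = if (status == "called") nt else 0,
               status = status)
}

#' Estimate tail lengths for a set of squiggles
#'
#' Runs normalize / segment / call for each squiggle and collects a per-read
#' table.
#'
#' @param squiggles list of \linkS4class{Squiggle} objects.
#' @param params parameter list from \code{\link{tailParams}}.
#' @return data.frame: read_id, tail_start, tail_end, samples_per_nt,
#'   tail_length (raw), tail_length_rounded, status, tail_is_valid.
#' @export
estimateTailLengths <- function(squiggles, params = tailParams()) {
  rows <- lapply(squiggles, function(sq) {
    seg <- segmentTail(normalizeSignal(sq), params)
    call <- callTailLength(sq, seg, params)
    data.frame(read_id = call@read_id,
               tail_start = if (is.null(seg)) NA_integer_ else seg@start,
               tail_end = if (is.null(seg)) NA_integer_ else seg@end,
               samples_per_nt = call@rate,
               tail_length = call@tail_length_nt,
               tail_length_rounded = round(call@tail_length_nt),
               status = call@status,
               tail_is_valid = call@status %in% c("called", "zero_tail"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
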