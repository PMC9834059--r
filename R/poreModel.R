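# Synthetic pore model construction.

# level plan (arbitrary pA-like units):
#   adapter stub            20   (outside the k-mer level range)
#   A-rich k-mers        ~  60   (polyA plateau in RNA-forward sense)
#   generic k-mers        72..128 on a 7-unit grid, de Bruijn colored
#   T-rich k-mers        ~ 140   (polyT plateau: the cDNA tail image)
.LEVEL_GRID <- seq(72, 128, by = 7)
.LEVEL_T_RICH <- 140
.LEVEL_A_RICH <- 60
.STUB_LEVEL <- 20
.STUB_SAMPLES <- 200L

#' Build a synthetic pore model
#'
#' Assigns every k-mer a mean current level and level sd. Generic k-mers are
#' placed on a coarse level grid by greedy coloring of the de Bruijn
#' adjacency, so that consecutive k-mers of any sequence differ in level and
#' each base transition produces a visible current step. k-mers with at
#' least k-1 T (the sequence context of a cDNA polyT tail, including
#' single-base interruptions) share a plateau far above the grid, and k-mers
#' with at least k-1 A a plateau below it, with small per-k-mer jitter so
#' homopolymer k-mers keep distinct levels.
#'
#' @param k k-mer length, one of 4, 5, 6 (default 5).
#' @param seed integer seed; the table is a pure function of (k, seed).
#' @return a \linkS4class{PoreModel}.
#' @export
#' @examples
#' pm <- makePoreModel(5, 7)
#' length(poreLevels(pm))  # 4^5
makePoreModel <- function(k = 5L, seed = 1L) {
  if (!is.numeric(k) || length(k) != 1L || !k %in% c(4, 5, 6))
    stop("'k' must be 4, 5 or 6")
  k <- as.integer(k)
  withSeed(seed, {
    km <- allKmers(k)
    nT <- baseCount(km, "T")
    nA <- baseCount(km, "A")
    nC <- baseCount(km, "C")
    nG <- baseCount(km, "G")
    # the polyT plateau covers pure T k-mers and single-C interruptions
    # (the cDNA context of internally modified tails); complementary rule
    # for the polyA plateau
    special_T <- nT == k | (nT == k - 1L & nC == 1L)
    special_A <- nA == k | (nA == k - 1L & nG == 1L)
    lev <- stats::setNames(numeric(length(km)), km)
    lev[special_T] <- .LEVEL_T_RICH + stats::runif(sum(special_T), -0.5, 0.5)
    lev[special_A] <- .LEVEL_A_RICH + stats::runif(sum(special_A), -0.5, 0.5)
    idx <- stats::setNames(seq_along(km), km)
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(km)) {
      if (special_T[i] || special_A[i]) next
      kmer <- km[i]
      nb <- c(paste0(substr(kmer, 2L, k), bases),
              paste0(bases, substr(kmer, 1L, k - 1L)))
      nb <- setdiff(nb, kmer)
      assigned <- idx[nb] < i | special_T[idx[nb]] | special_A[idx[nb]]
      used <- round(lev[nb[assigned]])
      free <- .LEVEL_GRID[!.LEVEL_GRID %in% used]
      if (!length(free)) free <- .LEVEL_GRID
      lev[i] <- if (length(free) == 1L) free else sample(free, 1L)
    }
    # keep the C/G homopolymer k-mers on distinct levels (A/T already are)
    cc <- strrep("C", k); gg <- strrep("G", k)
    if (round(lev[cc]) == round(lev[gg])) {
      free <- .LEVEL_GRID[.LEVEL_GRID != round(lev[cc])]
      nbg <- c(paste0(substr(gg, 2L, k), bases),
               paste0(bases, substr(gg, 1L, k - 1L)))
      free <- setdiff(free, round(lev[setdiff(nbg, gg)]))
      lev[gg] <- free[1L]
    }
    sds <- stats::setNames(stats::runif(length(km), 1.5, 2.5), km)
    methods::new("PoreModel", k = k, levels = lev, sds = sds,
                 seed = as.integer(seed))
  })
}
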