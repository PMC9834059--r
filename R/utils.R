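# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their arguments and never
#' disturb the session RNG.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# rolling mean over fixed window; returns length(x) - w + 1 values,
# value i summarising x[i .. i + w - 1]
rollMean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

# rolling unbiased variance over fixed window, same alignment as rollMean
rollVar <- function(x, w) {
  m1 <- rollMean(x, w)
  m2 <- rollMean(x * x, w)
  pmax(m2 - m1 * m1, 0) * w / (w - 1)
}

# all k-mers over the DNA alphabet, lexicographic in A<C<G<T
allKmers <- function(k) {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(b), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

baseCount <- function(seq, base) {
  nchar(seq) - nchar(gsub(base, "", seq, fixed = TRUE))
}

# reverse complement of a DNA character vector
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# cDNA-sense DNA string -> RNA-sense tail string (reverse complement, T -> U)
cdnaToRnaSense <- function(x) {
  chartr("T", "U", revComp(x))
}

rnaToCdnaSense <- function(x) {
  revComp(chartr("U", "T", x))
}

# polynomial rolling hash of a character scalar, for config fingerprints
contentHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
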