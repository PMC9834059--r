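# Shared fixtures, built once per test run.

fixture_pore <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePoreModel(5L, seed = 7L)
    cache
  }
})

fixture_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeTestTranscriptome(seed = 3L)
    cache
  }
})

# RNA-sense tail string for a designed class, mirrored from the simulator's
# spec so tests can state expectations independently
rna_tail <- function(class, len, n_mod = 3L) {
  if (class == "All-A") return(strrep("A", len))
  base <- sub(".*-", "", class)
  if (startsWith(class, "Term"))
    return(paste0(strrep("A", len - n_mod), strrep(base, n_mod)))
  stop("helper only builds All-A and Term-X tails")
}
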