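---
title: "Methods: polyA tail profiling from end-capture nanopore cDNA reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyA tail profiling from end-capture nanopore cDNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailcapR)
```

## The measurement problem

Template-switching ("end-capture") cDNA nanopore sequencing starts reverse
transcription at the RNA 3' terminus regardless of whether the molecule is
polyadenylated, so every read carries an image of the tail: in cDNA sense
the read is laid out as

```
[sequencing adapter] [31-nt end adapter] [tail, T-rich] [insert]
```

Two independent signals report on the tail. At the **raw-signal level**, a
homopolymer translocating through the pore produces a long stretch of
near-constant current whose duration is proportional to tail length. At the
**base-called level**, the tail appears as soft-clipped bases between the
adapter and the first reference-mapped base, which after
reverse-complementing (T→U) gives the tail sequence in RNA sense, terminal
additions last. Base-called homopolymers are unreliable in length (nanopore
base callers compress them), which is why length is estimated from signal
and composition from bases.

## Tail length from signal: the duration-ratio estimator

For a read with raw samples $x_1,\dots,x_N$ and $B$ base-called bases, the
estimator proceeds:

1. **Robust normalization.** $z_i = (x_i - \mathrm{med}(x)) / (1.4826\,
   \mathrm{MAD}(x))$, with an sd fallback when the MAD is zero. The constant
   1.4826 makes the scale comparable to an sd under normality.
2. **Adapter boundary.** The sequencing-adapter stub precedes the first
   base-called base at a level outside the k-mer range; its end is the
   largest lagged level change in the first quarter of the read (or a
   caller-supplied hint). Samples before the boundary never count as tail
   and are excluded from the rate denominator.
3. **Low-variance segment.** The normalized signal is lightly smoothed
   (moving mean, 5 samples) and a rolling variance (25 samples) is scanned
   after the boundary. Runs below threshold, merged across gaps of at most
   `max_gap_samples` (20), form candidate segments; the first run of at
   least `min_segment_samples` (60) after the boundary is the tail
   (tails are adapter-adjacent by construction of the chemistry). Run
   boundaries are widened to the full support of the rolling windows.
4. **Duration → nucleotides.** With $S$ tail samples and boundary $b$, a
   provisional tail base count $S / \hat r_0$ (whole-read rate
   $\hat r_0 = (N-b)/B$) is subtracted once, giving the non-tail rate
   $\hat r = (N - b - S)/(B - S/\hat r_0)$ in samples per nucleotide, and
   $\widehat{L} = S/\hat r + c$. No fixed translocation constant enters:
   the tail duration is compared with the duration of the rest of the same
   read, which makes the estimate invariant to per-read speed changes
   (tested by doubling the simulated dwell).

A read with no qualifying segment is a `zero_tail` call with length 0 —
absence of a tail is a value, not an error — and a rate outside
`rate_bounds` (3–40 samples/nt) flags the call `unreliable`.

### Why the variance threshold is adaptive

A fixed threshold in normalized units cannot serve all reads: the
normalization scale is itself data-dependent. For a 120-nt tail on a 199-nt
standard the tail is more than half the read, the median sits on the tail
level and the MAD collapses toward the noise scale — a threshold that works
there floods everything elsewhere. The threshold is therefore a multiple
(`noise_factor`, 32) of a robust per-read noise floor, estimated as
$\mathrm{med}(\Delta z^2)/2$ from first differences (which cancel levels
except at the ~10% of samples on event boundaries), divided by the
smoothing window, with floor `var_floor` ($10^{-5}$) so noiseless signals
still segment. Across simulated tails of 0–120 nt this keeps both error
directions controlled: every base step in adapter/insert breaks the mask,
while the homopolymer stays below threshold at any simulated noise level up
to several times the default.

### The context correction

With a 5-mer pore model and the library adapter ending `...TTC`, the flat
plateau of an $L$-nt tail spans exactly $L-1$ base events: three T-rich
adapter-context k-mers extend it on entry and $k-1$ events are lost on
exit. The constant $c = +1$ (`context_correction_nt`) restores unbiasedness
and is a property of the chemistry, not a tuning knob; the per-design
medians over the simulated standard series land within ~1.5% of 0, 15, 30,
60, 90, 120 nt. Tails shorter than ~4 nt leave no plateau at all and are
called `zero_tail` — a genuine resolution limit of duration-based callers.

## Tail composition from soft-clips

The soft-clip on the RNA-3'-end side of an alignment is
`[residual adapter][tail]` in cDNA sense. Processing:

* **Adapter trimming** (`trimEndAdapter`): local alignment of the 31-nt end
  adapter against the clip (Biostrings, one batched call per table);
  identity = matches / adapter length, trimmed when ≥ `end_threshold`
  (50%), plus `extra_end_trim` (0) bases inward.
* **A-content filter** (`filterAContent`): keep only tails with strictly
  more than 80% A in RNA sense — reads failing it are almost always
  untrimmed-adapter artifacts. The threshold is exclusive: a 30-nt tail
  with 24 A (80.0%) is discarded, 25 A (83.3%) kept.
* **7-way classification** (`classifyTail`) on the last 30 nt (shorter
  tails: their full length): pure A → `All-A`; non-A 3'-terminal base →
  `Term-{G,U,C}` (terminal additions are the biological signal, so terminal
  classification takes precedence when both kinds occur); otherwise
  `Int-{G,U,C}` by the most frequent non-A base, ties broken toward the 3'
  end. The labels partition every retained tail.
* **Positional profile** (`positionalProfile`): tails right-justified at
  the 3' terminus (position −1), per-position base probabilities over the
  last 20 nt; short tails contribute only to positions they cover.

One consequence worth stating: the strict `All-A` bin is single-substitution
sensitive. At a 2% per-base error rate the chance of an error-free 30-nt
window is $0.98^{30} \approx 55\%$, so `All-A` recovery is bounded by that
number while `Term-U`/`Int-G` designs stay above 90%. The tests assert
exactly this error-model behaviour rather than an unachievable blanket rate.

## 3'-end filtering, isoform assignment, expression

The chemistry reads the RNA 3'→5', so the cDNA read *starts* at the RNA 3'
end; after mapping, that end is the alignment **end** coordinate for
reverse-orientation records and the **start** for forward ones (stated once
here, tested in `test-transcript-assign.R`). All internal coordinates are
0-based half-open; SAM is converted on read, BED is native.

* `filterCompleteReads` keeps a read iff its 3' end lies within ±`window`
  (10, inclusive — "within" read inclusively) of an annotated exon end of a
  gene on the compatible strand; everything else is an incomplete or
  internally degraded product and goes to the rejects table with a reason.
* `assignToIsoform` assigns the candidate transcript minimizing
  |read 3' end − annotated 3' end| when that minimum is ≤ window; exact
  ties are `ambiguous`, never double-counted. assigned + unassigned +
  ambiguous always equals the input reads.
* `quantifyRpm` counts assigned reads per gene and scales to reads per
  million assigned; biotype is carried for breakdowns.

## Divergence statistics

`divergenceScan` tests each unit (gene, transcript, class) with at least two
groups of strictly more than `min_reads` (10) observations using the
Kruskal–Wallis test with tie correction (tail tables contain many zeros),
then Benjamini–Hochberg across tested units. For total $n \le 20$ the
chi-square approximation is poor, so the p value comes from seeded
Monte-Carlo permutation of group labels (B = 2000), cross-checked in the
tests against a complete-enumeration oracle at $n = 8$. Both the raw-p and
adjusted-q significant fractions are reported, because headline fractions
are commonly quoted at raw $P<\alpha$ while per-unit calls use q; the
`policy` field records which one drives the `significant` flag.

## Modification profiling

`buildPileup` counts per-site aligned bases, mismatches (deletions count as
mismatches — reverse-transcription drop events manifest as deletions or
truncations; insertions are ignored) and **drop-offs**, attributed to the
read's last aligned position in reverse-transcription direction (the end
opposite its RNA 3' end); drop-offs sum to the read count. Sites without
coverage report missing frequencies, never zero. `flagModifiedSites`
retains sites with mismatch frequency ≥ `mask_threshold` (0.1, inclusive at
the boundary: below 0.1 is masked) and co-reports the local drop-off rate.
`compareProfiles` contrasts two 3'-end-defined populations
(precursor-style vs processed-style) site by site; sites where both
frequencies are below the mask, or where either population has coverage
below `min_coverage` (20 — a frequency from a handful of reads is too noisy
to rank), are masked, and unmasked sites are ranked by |Δfrequency| so a
maturation-specific modification surfaces as the top outlier. No test on
the deltas is performed; a binomial test is a straightforward extension.

## What the simulator emulates — and what it does not

`makePoreModel` + `simulateSquiggle` generate: a 200-sample adapter stub at
a level outside the k-mer range; one event per base with the level of its
5-mer context; dwell from a shifted geometric (minimum 3 samples, mean
`dwell_mean`, truncated at 6× the mean — the untruncated tail produces
single-base events long enough to mimic short homopolymers, which no real
event detector would emit as one event); Gaussian current noise. Generic
k-mers are colored on a 9-level grid so that de Bruijn-adjacent k-mers
always differ (every base transition is a visible step); pure-T and
single-C-interrupted-T k-mers share a high plateau (complement rule for A),
which is what makes the internally interrupted standard segment as one
tail. `simulateAlignmentSet` generates soft-clipped alignments with
designed tails, substitution errors, optional adapter remnants,
controllable 3'-end offsets and optional mismatch hotspots.

Real data differ in ways the simulator does not model, so passing tests
bound algorithmic correctness, not platform performance: real pores have
~4000 distinguishable k-mer levels with measurement drift, real dwell
distributions are heavier-tailed and rate varies within a read, base-call
errors include indels (excluded by design in v1, so truth alignment stays
trivial), and real tails show slippage re-reads. The duration-ratio
principle is robust to uniform rate changes but not to rate *changes across
the read*, which is a known limitation of this estimator family.

## Problem sizes and determinism

Every generator is a pure function of its arguments including `seed`
(RNG state is saved and restored, so library code never perturbs a
session). The test suite and the acceptance script re-derive everything
from code: per-design parameter recovery uses 200 simulated reads per
standard (the medians are stable to well under a nucleotide at that size),
property suites use 10^4 tails, 500 null units and 100 seed replicates for
outlier detection. A full pipeline run on the default configuration (12
standards × 20 squiggles, 300 alignments) completes in well under a minute.

## Known limitations

* Tail lengths below ~4 nt are reported as zero (no plateau).
* The A-content filter and classification operate in RNA sense; the
  equivalent read-sense (T-content) convention would differ for tails with
  many non-A bases. The choice is exposed, not hidden.
* Mixed internal/terminal tails are classified terminal-first; the
  alternative convention is a one-line change (`classifyTail`).
* `divergenceScan` treats reads as exchangeable within unit × group;
  per-molecule duplicates (re-reads) would need collapsing upstream.
* The SAM reader supports the soft-clip + match records the simulator
  writes (substitution-only alignments), not arbitrary CIGARs.
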