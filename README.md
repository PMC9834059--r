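# tailcapR

PolyA tail profiling from end-capture (template-switching) nanopore cDNA
sequencing.

## The problem

Standard nanopore library preparations only capture polyadenylated RNA.
Template-switching cDNA sequencing instead initiates reverse transcription
at *any* RNA 3' end, placing the tail between a known 31-nt end adapter and
the insert of every cDNA read. That gives simultaneous access, per
molecule, to

* the **tail length** — the tail translocates as a homopolymer and leaves a
  long low-variance stretch of raw current;
* the **tail composition** — the base-called tail survives as soft-clipped
  bases next to the adapter, revealing terminal and internal non-A
  additions (uridylation, guanylation, ...);
* the **3' isoform identity** — the read's start coordinate is the RNA 3'
  end, so reads can be filtered for completeness and assigned to isoforms
  by 3'-end agreement with annotation;
* **RNA modifications** — Watson–Crick-disrupting bases (e.g. the
  hypermodified SSU rRNA pseudouridine) elevate reverse-transcription
  mismatches and drop-offs at the modified site.

tailcapR implements this downstream computation for R, plus a raw-signal
and alignment simulator with known ground truth (including the twelve
published synthetic cDNA tail standards), so the whole pipeline is testable
without sequencing data.

## The core estimator

For a read with `N` raw samples, `B` base-called bases, a detected adapter
boundary `b` and a tail segment of `S` samples, the tail length is obtained
by the duration-ratio principle — the tail's signal duration relative to
the duration of the rest of the same read:

    r̂₀ = (N − b) / B                      whole-read rate, samples/nt
    r̂  = (N − b − S) / (B − S/r̂₀)         non-tail rate after one refinement
    L̂  = S / r̂ + c                         c: k-mer context correction (+1)

The tail segment itself is the first run of rolling variance below an
adaptive threshold (a multiple of the read's robust noise floor) after the
adapter boundary, merged across short gaps so internally interrupted tails
stay one segment. Composition classification bins each retained tail
(strictly >80% A) on its last 30 nt into All-A, Int-G/U/C or Term-G/U/C,
terminal taking precedence; per-unit tail statistics use Kruskal–Wallis
with Benjamini–Hochberg correction; modification profiling contrasts
per-site mismatch frequencies between 3'-end-defined read populations.
Details and design rationale: `vignettes/tail-profiling.Rmd`.

## Worked example

Simulate reads from the 30-nt tail standard and estimate their tails from
signal:

```r
library(tailcapR)

reg  <- standardsRegistry()             # the 12 printed cDNA standards
pore <- makePoreModel(5, seed = 7)
sims <- simulateSquiggleSet(
  reg$full_sequence[reg$name == "cDNA_pA_standard_30"],
  pore, n = 50, dwell_mean = 10, noise_sd = 0.3, seed = 7)
calls <- estimateTailLengths(sims$squiggles)
head(calls[, c("read_id", "tail_start", "tail_end", "samples_per_nt",
               "tail_length", "status")], 4)
#>    read_id tail_start tail_end samples_per_nt tail_length status
#>  read_0001        432      699       9.738693    28.41641 called
#>  read_0002        459      815      10.587940    34.62316 called
#>  read_0003        465      835       9.316583    40.71413 called
#>  read_0004        487      755       9.271357    29.90623 called
median(calls$tail_length)
#> [1] 30.28963
```

Each row is one read: the tail segment spans `tail_start..tail_end` raw
samples, the per-read translocation rate is ~10 samples/nt (the simulated
dwell), and the per-read lengths scatter around the designed 30 nt with the
median recovering it to within a fraction of a nucleotide.

Composition, 3'-end filtering, isoform assignment and expression on a
simulated alignment set:

```r
anno <- makeTestTranscriptome(seed = 1)
sim  <- simulateAlignmentSet(anno, 300,
          tailSpec(c("All-A", "Term-U", "Int-G"),
                   lengths = c(40, 30, 50), probs = c(.6, .2, .2)),
          error_rate = 0.02, seed = 1, offsets = -15:15)
kept  <- filterCompleteReads(sim$alignments, anno, window = 10)
nrow(kept)
#> [1] 200          # of 300: reads ending >10 nt from an exon end are dropped
tails <- classifyTails(kept)
table(tails$class[tails$kept])
#>  All-A  Int-C  Int-G  Int-U Term-C Term-G Term-U
#>     71     13     48     12      6      3     46
ass <- assignReads(kept, anno, window = 10)
rpm <- quantifyRpm(ass, anno)
head(rpm, 3)
#>  gene_id        biotype count    rpm
#>   gene01 protein_coding    24 120000
#>   gene02        lincRNA    39 195000
#>   gene03 protein_coding    37 185000
```

With the uniform ±15 nt offsets, 200/300 reads end within the ±10 nt
window (≈ 21/31 of them, as expected); the designed classes dominate the
class table, with the 2% substitution rate scattering a predictable
fraction of All-A tails into the Int-\* bins.

A thin CLI over the same functions lives at `inst/scripts/tailcap`
(`tailcap all --out run1 --seed 1` runs simulate → taillen → tailcomp →
assign → stats → modprofile and writes TSV/JSON outputs stamped with the
configuration hash).

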