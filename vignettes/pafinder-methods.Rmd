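---
title: "Calling poly(A) tail lengths from direct tail sequencing: methods and design"
author: "pafinder authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling poly(A) tail lengths from direct tail sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafinder)
```

## The problem

Poly(A) tails — homopolymeric adenosine runs appended to the 3' end of most
eukaryotic mRNAs — regulate transcript stability and translation. Direct
poly(A) sequencing libraries read each cDNA 5'→3' from the transcript body
through the 3'UTR into the tail, so a single Illumina read contains, in
order: a genomic *anchor* (the 3'UTR suffix ending at the cleavage site),
the poly(A) tail, and — when the tail is short enough — the 3' adaptor.
`pafinder` turns such reads into per-read tail lengths and per-gene median
tail profiles.

Two instrument artifacts complicate the picture. On two-channel chemistry,
loss of signal is called as G, so exhausted templates end in long G runs.
And the strong homopolymer A signal *bleeds* into the cycles that read the
adaptor, inflating apparent tail lengths; the base quality collapses
sharply at the tail/adaptor junction, which is the signal the optional
quality filter exploits.

## The calling procedure

For each read (all coordinates 1-based inclusive; the package uses the
R/IRanges interval idiom throughout, converting at the GTF/SAM boundary
where the formats already match it):

1. **Trim** (`trim_read`): an optional 5'-adaptor prefix (after any
   template-switch G run) is removed when it matches within the configured
   error rate, and everything from the first G run of ≥ `polyG_min_run`
   (default 10) nt onward is dropped as a dark-signal artifact. The 3'
   adaptor is deliberately *not* trimmed — it is the evidence that a tail
   was fully sequenced.
2. **Preliminary region** (`find_preliminary_region`): a 9-nt window slides
   5'→3' and a 6-nt window 3'→5'; the first window on each side with at
   most 1 non-A base delimits the preliminary poly(A) region. Regions
   shorter than 10 nt are discarded. The published description gives both
   error rates (0.1 on the 9-mer, 0.2 on the 6-mer, which floor to 0 and 1
   mismatches) and a flat "1 mismatch for each search"; the package
   defaults to 1 mismatch on both anchors and exposes the rate-based
   budgets as `anchor5_error_rate`/`anchor3_error_rate` alternatives.
3. **Refinement** (`refine_region`): non-A runs of ≥ 5 nt split the region;
   each fragment is stripped to start and end on an adenosine; fragments
   lacking 10 consecutive adenosines are rejected; the longest surviving
   fragment (ties: 5'-most, contiguous with the mapped anchor) is the
   tail. This removes genome-templated internal A stretches while
   tolerating isolated sequencing errors inside the tail. Candidates are
   filtered *before* the longest is chosen, which makes the procedure
   exactly equivalent to choosing the longest subinterval that starts and
   ends on A, contains no splitting run and has the pure-A core — the
   property the oracle-equivalence test verifies exhaustively.
4. **Quality-bleeding filter** (`apply_quality_bleed_filter`, opt-in): the
   tail is scanned 5'→3' with a 3-position window; at the first window
   whose mean Phred score is strictly below 25 the tail is truncated just
   before the window. Because a bled adenosine carries the collapsed
   post-junction quality, this removes bleeding at its source. The filter
   is off by default and enabled by the NovaSeq preset, where bleeding is
   most pronounced. Note the boundary behaviour: when the quality drop is
   a step function, the first sub-threshold window starts at the *last*
   high-quality base (e.g. mean(37, 10, 10) = 19 < 25), so the truncated
   tail ends one base before the step; the ≤ 2 nt accuracy checks absorb
   this deliberate, rule-faithful off-by-one.
5. **Adaptor detection** (`detect_adaptor`): the first 20 nt of the 3'
   adaptor are compared at offsets 0–3 downstream of the tail end; the
   adaptor is found when the Hamming distance is at most
   `floor(error_rate × 20)` (default rate 0.2). The small offset window
   absorbs residual bled bases between tail and adaptor; detection is
   provably monotone in the error rate. A tail that reaches the read end
   has no detectable adaptor and reports the *visible* length — no
   extrapolation is attempted.

The sequence upstream of the preliminary region is the anchor used for
gene assignment (`map_anchors` for toy references — an exhaustive ungapped
two-strand Hamming scan, ≥ 20 nt anchors, ≤ 2 mismatches, unique =
a single minimum-mismatch locus — or `import_alignments` for alignments
from a real spliced aligner). The anchor's 3'-most aligned base is the
inferred cleavage/polyadenylation position; `tts_distance` reports its
strand-aware signed distance to the nearest annotated transcript end,
excluding mitochondrial chromosomes by default.

Because the fuzzy 5' anchor window may open one base before the tail, the
exposed anchor typically stops one base short of the junction, and the
inferred cleavage positions sit a base or two upstream of the annotated
TTS even on perfect data — a property of the windowed search worth
remembering when interpreting TTS-distance distributions.

## Aggregation

Per-gene medians (`gene_medians`) use the lower-median convention: for
even read counts the lower of the two central values, so every reported
median is an observed integer tail length. `tail_histogram` (half-open
bins), `cumulative_fraction` (right-continuous ECDF),
`base_composition_by_cycle`, `junction_composition` (reads re-anchored at
their called tail end; the decay of the A fraction over post-tail offsets
quantifies bleeding) and `adaptor_detection_sweep` produce the standard
figure-ready tables. The sweep's default denominator is *all* retained
tail reads, so tails running to the read end count as undetected — this
reproduces the observation that longer tails show lower adaptor recovery;
`eligible_only = TRUE` restricts to reads with a full probe length of
downstream sequence.

## Spike-ins

The two published length standards are built in
(`spikein_default_specs()`): A40 and A120, each behind a
construct-specific 5' adaptor whose printed sequence starts with the 20-nt
T7 promoter. The transcribed adaptor is the printed sequence minus the
promoter — 40 nt for both constructs, reconciling the "40-nt adaptor" and
"39-nt adaptor" accountings (the latter excludes the terminal adenosine of
the A120 adaptor, which merges into the tail). Spike-in reads are
retrieved by fuzzy matching of the transcribed adaptor within the first
`library_prefix_len + 4` read positions, with the same 2-mismatch budget
used for anchor mapping. `spikein_profile`
constrains the preliminary search to start no earlier than the adaptor's
final base, so the A120 arithmetic comes out as published: on 150-nt reads
the visible tail is 104 spike-in adenosines plus the adaptor's terminal A
= 105 nt; on 250-nt reads the full 120-nt tail plus that terminal A = 121
nt.

## The simulator

`simulate_reads` generates reads with the statistical structure the caller
assumes: per-read anchors are 3'UTR suffixes ending at the TTS of a toy
genome (`make_toy_genome`), per-gene tail lengths are integer truncated
normals, qualities are `qual_hi` (37) through the true tail and `qual_lo`
(10) beyond the junction, and with probability `bleed_prob` a read gains a
geometric number (support 1, 2, …; mean `1/bleed_len_geom_p`, default 4)
of spurious low-quality adenosines before the adaptor. Substitutions are
uniform at `substitution_rate`. The defaults — 20,000 reads, 50 genes,
150-nt reads, 3'UTRs of 60–120 nt, anchors of 25–40 nt, gene mean tails
uniform in 20–80 nt with sd 5, substitution rate 0.001 — are the package's
reference validation conditions and are used as-is by the accuracy tests.

Two generator design choices keep simulation truth identifiable:

* every 3'UTR 20-mer is unique across genes, so noise-free anchors map
  uniquely;
* each 3'UTR ends with five non-A bases. The caller, by construction,
  merges genomic adenosines into the tail whenever fewer than
  `nonA_split_run` non-A bases separate them from it (exactly as the A120
  adaptor's terminal A merges); a boundary at least as long as the split
  threshold is therefore the precise condition under which true and called
  tails are directly comparable. Real transcripts offer no such guarantee
  — genomic A's at the cleavage site are genuinely indistinguishable from
  tail, and passing simulations bound only the algorithmic error, not this
  biological ambiguity.

The simulator does not model oligo(dT) capture bias (longer-tailed RNAs
enrich better, which biases real libraries toward longer tails), PCR
duplicates, instrument-specific error spectra, or RNase fragmentation
biology (anchors always terminate at the TTS); the bleeding model is a
simple geometric stand-in whose parameters are config-exposed, not claimed
measurements. The default 3' adaptor is the standard Illumina small-RNA
adaptor `TGGAATTCTCGGGTGCCAAGG`, chosen because the kit adaptor used in
the original libraries is not printed; its non-A junction bases also make
the noise-free junction exactly recoverable.

## Numerical and edge-case conventions

* N bases count as mismatches against A in every fuzzy comparison
  (conservative; relevant sources never emit N inside tails).
* Quality encoding is fixed to Phred+33; files whose scores decode above
  60 are rejected as likely Phred+64 rather than silently re-scaled.
* Mismatch budgets derived from error rates are floored.
* Equal-length refinement candidates resolve 5'-most; the quality filter
  uses a strict `< 25` inequality; a truncated tail is re-stripped to end
  on an adenosine and re-checked against the length and pure-run minima.
* A fully trimmed read, or one without anchors, is a recorded discard
  (`no_prelim`), never an error.
* End-2 mates are ignored throughout: the read layout that carries the
  tail is end-1 only.

## Problem sizes used in the checks

The test suite validates refinement against a brute-force subinterval
oracle on every {A,C} string up to length 14 (32,766 strings) plus 10,000
random 30-nt A-rich strings; parameter recovery runs the full reference
conditions (20,000 reads, 50 genes) and requires every gene with ≥ 20
reads to recover its true median within ±2 nt; the bleeding check runs
6,000 reads at `bleed_prob = 0.5` and requires the filtered sample median
within 2 nt of truth while the unfiltered one overestimates; sweep
monotonicity is checked over 20 random simulator configurations. These
sizes were chosen to exercise the asymptotics that matter while keeping
the default check fast on a laptop.

## Limitations

The built-in mapper is ungapped and unspliced and guarded to ≤ 10 Mb
references — real genomes go through an external spliced aligner and SAM
import. Tail lengths are never extrapolated beyond the read end, so the
observable tail spectrum is capped at `read_len` minus the anchor and
adaptor footprint. Mixed (G/U) tailing is not classified. Indel-tolerant
adaptor matching is not implemented; detection is pure Hamming with a
small offset window.
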