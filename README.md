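# pafinder

Poly(A) tail length profiling from direct tail sequencing reads.

Most eukaryotic mRNAs carry a 3' homopolymeric adenosine tail whose length
regulates transcript stability and translation. Direct poly(A) sequencing
libraries read each cDNA 5'→3' from the transcript body through the 3'UTR
into the tail, so a single Illumina read contains a genomic **anchor**
(the 3'UTR suffix ending at the cleavage site), the **poly(A) tail**, and
— for short enough tails — the **3' adaptor**. `pafinder` calls the tail
in every such read and aggregates per-gene median tail lengths. It is
written for transcriptomics researchers running bulk or single-cell
poly(A) profiling libraries on Illumina platforms.

## The algorithm

Per read, after trimming dark-signal poly(G) and any 5' adaptor:

1. **Fuzzy anchors.** A 9-nt window slid 5'→3' and a 6-nt window slid
   3'→5' (each tolerating 1 non-A) delimit the *preliminary* poly(A)
   region; regions < 10 nt are discarded.
2. **Refinement.** Non-A runs ≥ 5 nt split the region; each fragment is
   stripped to A boundaries and must contain ≥ 10 consecutive adenosines;
   the longest surviving fragment (ties 5'-most) is the tail, with
   `tail_len = end − start + 1`.
3. **Quality-bleeding filter** (opt-in; default in the NovaSeq preset).
   Homopolymer signal bleeds into the adaptor while base quality collapses
   at the junction, so the tail is truncated before the first 3-position
   window whose mean Phred score drops below 25.
4. **Adaptor detection.** The first 20 nt of the 3' adaptor are scanned at
   offsets 0–3 downstream of the tail with a Hamming budget of
   `floor(error_rate × 20)`; a detected adaptor certifies a fully
   sequenced tail.

The anchor upstream of the tail (≥ 20 nt, ≤ 2 mismatches) assigns the read
to a gene — via the built-in exhaustive mapper for toy references or via
SAM/BAM import from any spliced aligner — and per-gene medians use the
lower-median convention, so reported medians are observed integer lengths.
A synthetic read simulator with a toy genome, junction quality collapse
and a geometric bleeding model makes every stage verifiable without
external data, and the two published spike-in length standards (40-nt and
120-nt tails) are built in.

## Worked example

Simulate a small dataset, call tails, map anchors, and profile genes:

```r
library(pafinder)

cfg   <- sim_config(seed = 101, n_reads = 2000, n_genes = 10)
paths <- simulate_dataset(cfg, "demo")          # reads.fq, truth.tsv, genome.fa, genes.gtf

reads <- read_fastq(paths$fastq)
calls <- call_tails(reads, adaptor3 = cfg$adaptor3)
sum(calls$discard_reason == "none")
#> [1] 2000

ann <- read_annotation(paths$gtf)
asn <- assign_genes(map_anchors(calls, paths$fasta), ann)
gm  <- gene_medians(calls, asn)
head(gm, 5)
#>   gene_id n_reads median_tail_len
#> 1 gene001     196              33
#> 2 gene002     221              72
#> 3 gene003     198              47
#> 4 gene004     213              71
#> 5 gene005     199              42
attr(gm, "sample_median")
#> [1] 53
```

Each row is one gene: `n_reads` tail-containing reads were uniquely
assigned to it, and `median_tail_len` is the median of their called tail
lengths in nucleotides. On this noise-level (substitution rate 0.001) the
called per-gene medians equal the simulated true medians exactly.

The same pipeline is available from a shell:

```sh
inst/scripts/pafinder simulate --out-dir demo --seed 101 --n-reads 2000 --n-genes 10
inst/scripts/pafinder call --fastq demo/reads.fq --out demo/calls.tsv \
    --adaptor3 TGGAATTCTCGGGTGCCAAGG
inst/scripts/pafinder map --calls demo/calls.tsv --reference demo/genome.fa \
    --gtf demo/genes.gtf --out demo/assign.tsv
inst/scripts/pafinder stats --calls demo/calls.tsv --assign demo/assign.tsv \
    --out-dir demo/stats
```

## Layout

- `R/` — caller (`tailcall`), I/O (`fastq`, `annotation`, `alignments`,
  `calls_io`), mapping (`anchor_map`), statistics (`profiles`), spike-ins
  (`spikein`), simulator (`simulate`), CLI (`cli`).
- `vignettes/pafinder-methods.Rmd` — model, parameters, design decisions
  and limitations.
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles.
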