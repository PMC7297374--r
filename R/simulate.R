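# Synthetic-data generator. Emulates the read structure the caller assumes:
# a genomic anchor (3'UTR suffix ending at the TTS), the poly(A) tail, an
# optional run of bled low-quality adenosines, and the 3' adaptor; per-cycle
# quality collapses from qual_hi to qual_lo at the tail/adaptor junction.
# Deterministic given the config seed.

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# uniform integers in [lo, hi]; robust to lo == hi (unlike sample(seq(...)))
.sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

.revcomp <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

#' Simulation configuration
#'
#' Defaults define the reference validation conditions: a 50-gene toy
#' genome with 60-120 nt 3'UTRs, 150-nt reads, per-gene mean tail lengths
#' uniform in 20-80 nt with an sd of 5 nt (truncated at 0, integer),
#' anchors of 25-40 nt, a per-base substitution rate of 0.001, Phred 37
#' before and Phred 10 after the tail/adaptor junction, and no signal
#' bleeding unless requested. The 3' adaptor defaults to the standard
#' Illumina small-RNA 3' adaptor.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_reads Number of reads to simulate.
#' @param read_len Read length in nt (150 and 250 mirror the common
#'   platform presets).
#' @param n_genes Number of toy genes.
#' @param utr3_len Range (min, max) of 3'UTR lengths (nt).
#' @param tail_mean_range Range of per-gene mean tail lengths (nt).
#' @param tail_sd Within-gene tail-length sd (nt).
#' @param anchor_len Range of per-read anchor lengths (nt).
#' @param adaptor3 3'-adaptor sequence appended after the tail.
#' @param substitution_rate Per-base substitution probability.
#' @param qual_hi,qual_lo Phred scores before/after the junction.
#' @param bleed_prob Probability that a read gains spurious adenosines past
#'   the true tail.
#' @param bleed_len_geom_p Geometric parameter of the bleed run length
#'   (support 1, 2, ...; mean `1/p`).
#' @return A `pa_sim_config` object.
#' @export
sim_config <- function(seed = 1L, n_reads = 20000L, read_len = 150L,
                       n_genes = 50L, utr3_len = c(60L, 120L),
                       tail_mean_range = c(20, 80), tail_sd = 5,
                       anchor_len = c(25L, 40L),
                       adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                       substitution_rate = 0.001,
                       qual_hi = 37L, qual_lo = 10L,
                       bleed_prob = 0, bleed_len_geom_p = 0.25) {
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              read_len = as.integer(read_len), n_genes = as.integer(n_genes),
              utr3_len = as.integer(utr3_len),
              tail_mean_range = as.numeric(tail_mean_range),
              tail_sd = as.numeric(tail_sd),
              anchor_len = as.integer(anchor_len),
              adaptor3 = toupper(adaptor3),
              substitution_rate = as.numeric(substitution_rate),
              qual_hi = as.integer(qual_hi), qual_lo = as.integer(qual_lo),
              bleed_prob = as.numeric(bleed_prob),
              bleed_len_geom_p = as.numeric(bleed_len_geom_p))
  probs <- c(cfg$substitution_rate, cfg$bleed_prob, cfg$bleed_len_geom_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$read_len < 30L)
    stop("read_len too short to hold an anchor and a minimal tail")
  if (cfg$qual_hi > 60L || cfg$qual_lo < 0L)
    stop("quality levels must be Phred scores in [0, 60]")
  structure(cfg, class = "pa_sim_config")
}

#' Generate a deterministic toy genome with annotation
#'
#' Builds one chromosome carrying `n_genes` genes on alternating strands.
#' Each gene has a 30-nt 5'UTR, a 60-nt CDS (every third gene split by a
#' 60-nt intron) and a 3'UTR of random length in `utr3_len`. 3'UTR
#' sequences are random with two constraints that keep simulation truth
#' identifiable: every 20-mer is unique across genes (guaranteeing unique
#' anchor mapping) and the final five 3'UTR bases are non-A -- the caller
#' merges genomic adenosines within a sub-threshold non-A stretch of the
#' cleavage site into the tail by construction, so a boundary of at least
#' `nonA_split_run` non-A bases is exactly the condition under which true
#' and called tails are directly comparable. Per-gene mean
#' tail lengths are drawn here so they are part of the genome truth.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional directory; when given, `genome.fa` and `genes.gtf`
#'   are written there.
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `features`
#'   (GTF-ready [GenomicRanges::GRanges]), `genes` (data frame with
#'   `gene_id`, `strand`, `start`, `end`, `tts`, `utr3_seq`, `tail_mean`)
#'   and, when written, `fasta_path` / `gtf_path`.
#' @export
make_toy_genome <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  utr5_len <- 30L; cds_len <- 60L; intron_len <- 60L; gap_len <- 100L
  n <- config$n_genes
  chrom_parts <- character(0)
  feat_rows <- list()
  gene_rows <- list()
  kmer_seen <- character(0)
  offset <- 0L
  for (i in seq_len(n)) {
    gid <- sprintf("gene%03d", i)
    tid <- sprintf("tx%03d", i)
    strand <- if (i %% 2L == 0L) "-" else "+"
    has_intron <- i %% 3L == 0L
    u3_len <- .sample_range(config$utr3_len[1L], config$utr3_len[2L], 1L)
    repeat {
      # the last 5 UTR bases are non-A: a non-A run at least as long as the
      # caller's split threshold is the condition under which genomic and
      # tail adenosines are separable, keeping simulation truth identifiable
      u3 <- paste0(.rand_dna(u3_len - 5L),
                   paste(sample(c("C", "G", "T"), 5L, replace = TRUE),
                         collapse = ""))
      kmers <- substring(u3, seq_len(u3_len - 19L), 20:u3_len)
      if (!anyDuplicated(kmers) && !any(kmers %in% kmer_seen)) break
    }
    kmer_seen <- c(kmer_seen, kmers)
    u5 <- .rand_dna(utr5_len)
    cds <- .rand_dna(cds_len)
    gap <- .rand_dna(gap_len)
    if (has_intron) {
      half <- cds_len %/% 2L
      tx_parts <- c(u5, substr(cds, 1L, half), substr(cds, half + 1L,
                                                      cds_len), u3)
      genic <- paste0(u5, substr(cds, 1L, half), .rand_dna(intron_len),
                      substr(cds, half + 1L, cds_len), u3)
      # transcript-orientation intervals within the genic sequence
      exon_iv <- list(c(1L, utr5_len + half),
                      c(utr5_len + half + intron_len + 1L, nchar(genic)))
      cds_iv <- list(c(utr5_len + 1L, utr5_len + half),
                     c(utr5_len + half + intron_len + 1L,
                       utr5_len + half + intron_len + half))
    } else {
      genic <- paste0(u5, cds, u3)
      exon_iv <- list(c(1L, nchar(genic)))
      cds_iv <- list(c(utr5_len + 1L, utr5_len + cds_len))
    }
    glen <- nchar(genic)
    gstart <- offset + gap_len + 1L
    gend <- gstart + glen - 1L
    chrom_parts <- c(chrom_parts, gap,
                     if (strand == "+") genic else .revcomp(genic))
    offset <- gend
    to_genomic <- function(iv) {
      if (strand == "+") c(gstart + iv[1L] - 1L, gstart + iv[2L] - 1L)
      else c(gend - iv[2L] + 1L, gend - iv[1L] + 1L)
    }
    mk <- function(type, iv) data.frame(
      start = to_genomic(iv)[1L], end = to_genomic(iv)[2L], type = type,
      gene_id = gid, transcript_id = tid, strand = strand,
      stringsAsFactors = FALSE)
    rows <- list(mk("gene", c(1L, glen)), mk("transcript", c(1L, glen)))
    for (iv in exon_iv) rows <- c(rows, list(mk("exon", iv)))
    for (iv in cds_iv) rows <- c(rows, list(mk("CDS", iv)))
    feat_rows <- c(feat_rows, rows)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, tx_id = tid, strand = strand, start = gstart,
      end = gend, tts = if (strand == "+") gend else gstart,
      utr3_seq = u3,
      tail_mean = stats::runif(1L, config$tail_mean_range[1L],
                               config$tail_mean_range[2L]),
      stringsAsFactors = FALSE)
  }
  chrom_parts <- c(chrom_parts, .rand_dna(gap_len))
  chrom <- paste(chrom_parts, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom, "chr1"))
  seqinfo <- GenomeInfoDb::Seqinfo("chr1", nchar(chrom))
  if (length(feat_rows)) {
    feat <- do.call(rbind, feat_rows)
    features <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(feat$start, feat$end), strand = feat$strand,
      type = feat$type, source = "pafinder_sim", gene_id = feat$gene_id,
      transcript_id = feat$transcript_id, seqinfo = seqinfo)
    genes <- do.call(rbind, gene_rows)
  } else {
    features <- GenomicRanges::GRanges(seqinfo = seqinfo)
    genes <- data.frame(gene_id = character(), tx_id = character(),
                        strand = character(), start = integer(),
                        end = integer(), tts = integer(),
                        utr3_seq = character(), tail_mean = numeric(),
                        stringsAsFactors = FALSE)
  }
  out <- list(genome = genome, features = features, genes = genes)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$fasta_path <- file.path(dir, "genome.fa")
    out$gtf_path <- file.path(dir, "genes.gtf")
    Biostrings::writeXStringSet(genome, out$fasta_path)
    # phase is irrelevant downstream; suppress the exporter's reminder
    suppressWarnings(rtracklayer::export(features, out$gtf_path,
                                         format = "gtf"))
  }
  out
}

.draw_bleed <- function(n, prob, geom_p) {
  bleeds <- stats::runif(n) < prob
  len <- integer(n)
  if (any(bleeds))
    len[bleeds] <- stats::rgeom(sum(bleeds), geom_p) + 1L
  len
}

.apply_substitutions <- function(bases, rate) {
  if (rate <= 0) return(bases)
  n_sub <- stats::rbinom(length(bases), nchar(bases), rate)
  for (i in which(n_sub > 0L)) {
    pos <- sample.int(nchar(bases[i]), n_sub[i])
    chars <- strsplit(bases[i], "")[[1L]]
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[p]), 1L)
    bases[i] <- paste(chars, collapse = "")
  }
  bases
}

# assemble reads from per-read components; shared by the genomic and
# spike-in simulators
.assemble_reads <- function(prefix, tail_len, bleed_len, adaptor3, read_len,
                            qual_hi, qual_lo) {
  n <- length(prefix)
  fill <- if (is.null(adaptor3) || !nzchar(adaptor3)) rep("", n)
          else rep(strrep(adaptor3, ceiling(read_len / nchar(adaptor3)) + 1L),
                   n)
  bases <- paste0(prefix, strrep("A", tail_len + bleed_len), fill)
  bases <- substr(bases, 1L, read_len)
  hi_len <- pmin(nchar(prefix) + tail_len, nchar(bases))
  qual <- paste0(strrep(intToUtf8(qual_hi + 33L), hi_len),
                 strrep(intToUtf8(qual_lo + 33L), nchar(bases) - hi_len))
  list(bases = bases, qual = qual)
}

#' Simulate reads from a toy genome
#'
#' Each read is a 3'UTR suffix ending at the TTS (the anchor), the true
#' poly(A) tail, optionally a run of bled low-quality adenosines, and the
#' 3' adaptor repeated to the read end, truncated at `read_len`. Qualities
#' are `qual_hi` through the true tail and `qual_lo` beyond the junction;
#' substitutions are applied uniformly at `substitution_rate`.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [make_toy_genome()] (regenerated from `config`
#'   when omitted).
#' @return List with `reads` (read table) and `truth` (data frame:
#'   `read_id`, `gene_id`, `true_tail_len`, `bled_extra_As`,
#'   `adaptor_in_read`, `anchor_len`).
#' @export
simulate_reads <- function(config = sim_config(), genome = NULL) {
  if (is.null(genome)) genome <- make_toy_genome(config)
  set.seed(config$seed + 1L)
  n <- config$n_reads
  g <- sample.int(nrow(genome$genes), n, replace = TRUE)
  alen <- .sample_range(config$anchor_len[1L], config$anchor_len[2L], n)
  alen <- pmin(alen, nchar(genome$genes$utr3_seq[g]))
  u3 <- genome$genes$utr3_seq[g]
  anchor <- substr(u3, nchar(u3) - alen + 1L, nchar(u3))
  tail_len <- pmax(0L, as.integer(round(stats::rnorm(
    n, genome$genes$tail_mean[g], config$tail_sd))))
  bleed_len <- .draw_bleed(n, config$bleed_prob, config$bleed_len_geom_p)
  asm <- .assemble_reads(anchor, tail_len, bleed_len, config$adaptor3,
                         config$read_len, config$qual_hi, config$qual_lo)
  bases <- .apply_substitutions(asm$bases, config$substitution_rate)
  read_id <- sprintf("read%06d", seq_len(n))
  reads <- structure(data.frame(read_id = read_id, bases = bases,
                                qual = asm$qual, stringsAsFactors = FALSE),
                     class = c("pa_reads", "data.frame"))
  probe <- min(nchar(config$adaptor3), 20L)
  truth <- data.frame(
    read_id = read_id, gene_id = genome$genes$gene_id[g],
    true_tail_len = tail_len, bled_extra_As = bleed_len,
    adaptor_in_read = alen + tail_len + bleed_len + probe <= config$read_len,
    anchor_len = alen, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate spike-in reads
#'
#' Reads are `library_prefix_len` non-templated Gs, the transcribed 5'
#' adaptor, `expected_tail_len` adenosines, optionally bled extra
#' adenosines and the 3' adaptor, truncated at `read_len`. With
#' `adaptor3 = NULL` the read simply ends after the tail (shorter than
#' `read_len` when the construct is short).
#'
#' @param spec A `pa_spikein` object.
#' @param n Number of reads.
#' @param read_len Read length (nt).
#' @param adaptor3 3'-adaptor to append, or `NULL`.
#' @param bleed_prob,bleed_len_geom_p,substitution_rate,qual_hi,qual_lo
#'   Noise switches as in [sim_config()]; noise-free by default.
#' @param seed Optional seed (the caller's ambient RNG state is used when
#'   `NULL`).
#' @return List with `reads` and `truth` as in [simulate_reads()] (gene_id
#'   holds the spike-in name).
#' @export
simulate_spikein_reads <- function(spec, n, read_len = 150L, adaptor3 = NULL,
                                   bleed_prob = 0, bleed_len_geom_p = 0.25,
                                   substitution_rate = 0,
                                   qual_hi = 37L, qual_lo = 10L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prefix <- rep(paste0(strrep("G", spec$library_prefix_len),
                       spec$transcribed_adaptor), n)
  tail_len <- rep(spec$expected_tail_len, n)
  bleed_len <- .draw_bleed(n, bleed_prob, bleed_len_geom_p)
  asm <- .assemble_reads(prefix, tail_len, bleed_len, adaptor3, read_len,
                         qual_hi, qual_lo)
  bases <- .apply_substitutions(asm$bases, substitution_rate)
  read_id <- sprintf("%s_read%06d", spec$name, seq_len(n))
  reads <- structure(data.frame(read_id = read_id, bases = bases,
                                qual = asm$qual, stringsAsFactors = FALSE),
                     class = c("pa_reads", "data.frame"))
  truth <- data.frame(
    read_id = read_id, gene_id = spec$name, true_tail_len = tail_len,
    bled_extra_As = bleed_len,
    adaptor_in_read = !is.null(adaptor3) &
      nchar(prefix) + tail_len + bleed_len + 20L <= read_len,
    anchor_len = nchar(prefix), stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a complete dataset to disk
#'
#' Writes `reads.fq`, `truth.tsv`, `genome.fa` and `genes.gtf` into `dir`.
#' Outputs are byte-identical across runs with the same config.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  genome <- make_toy_genome(config, dir = dir)
  sim <- simulate_reads(config, genome)
  fq <- file.path(dir, "reads.fq")
  truth <- file.path(dir, "truth.tsv")
  write_fastq(sim$reads, fq)
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fastq = fq, truth = truth, fasta = genome$fasta_path,
                 gtf = genome$gtf_path))
}
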