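# Independent oracles and small fixture builders used across the suite.

hamming_chr <- function(a, b) sum(charToRaw(a) != charToRaw(b))

random_dna <- function(n, prob = NULL, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

one_read <- function(bases, q = 37L) {
  data.frame(read_id = "r1", bases = bases,
             qual = strrep(intToUtf8(q + 33L), nchar(bases)),
             stringsAsFactors = FALSE)
}

# brute-force refinement oracle: the longest subinterval of [start, end]
# that starts and ends on A, contains no non-A run >= nonA_split_run, has a
# pure-A run >= min_pure_A_run and is >= min_prelim_len long; ties 5'-most.
# Returns c(start, end) in absolute coordinates or NULL.
oracle_refine <- function(bases, start, end, p = pa_params()) {
  v <- strsplit(substr(bases, start, end), "")[[1]] == "A"
  L <- length(v)
  best <- NULL
  for (i in seq_len(L)) {
    if (!v[i]) next
    for (j in i:L) {
      if (!v[j]) next
      r <- rle(v[i:j])
      if (any(!r$values & r$lengths >= p$nonA_split_run)) next
      if (max(c(0L, r$lengths[r$values])) < p$min_pure_A_run) next
      if (j - i + 1L < p$min_prelim_len) next
      if (is.null(best) || (j - i) > (best[2L] - best[1L])) best <- c(i, j)
    }
  }
  if (is.null(best)) NULL else best + start - 1L
}

# naive all-positions Hamming mapper: every locus on either strand of every
# reference sequence with <= max_mm mismatches
oracle_map_scan <- function(anchor, refs, max_mm) {
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  hits <- list()
  for (nm in names(refs)) {
    subject <- refs[[nm]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") anchor else revcomp(anchor)
      k <- nchar(pat)
      for (s in seq_len(nchar(subject) - k + 1L)) {
        mm <- hamming_chr(substr(subject, s, s + k - 1L), pat)
        if (mm <= max_mm)
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = nm, strand = strand, start = s, end = s + k - 1L,
            n_mm = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) NULL else do.call(rbind, hits)
}

# sliding-window mean quality truncation oracle (independent re-statement
# of the QC rule): first window of w consecutive tail positions with mean
# score < thr; the tail keeps everything before that window
oracle_qc_end <- function(scores, start, end, w = 3L, thr = 25) {
  if (end - start + 1L < w) return(end)
  for (s in start:(end - w + 1L)) {
    if (mean(scores[s:(s + w - 1L)]) < thr) return(s - 1L)
  }
  end
}

write_lines_file <- function(lines, ext = "") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy two-gene GTF used by the annotation and assignment tests: a
# plus-strand 3-exon coding transcript (UTRs to be derived), a minus-strand
# coding transcript, and a second plus-strand transcript whose intron
# overlaps the first transcript's 3'UTR
toy_gtf <- function() {
  attr1 <- 'gene_id "g1"; transcript_id "t1";'
  attr2 <- 'gene_id "g2"; transcript_id "t2";'
  attr3 <- 'gene_id "g3"; transcript_id "t4";'
  write_lines_file(c(
    paste("chr1", "toy", "transcript", 101, 400, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "toy", "exon", 101, 150, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "toy", "exon", 201, 260, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "toy", "exon", 301, 400, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "toy", "CDS", 121, 150, ".", "+", "0", attr1, sep = "\t"),
    paste("chr1", "toy", "CDS", 201, 260, ".", "+", "0", attr1, sep = "\t"),
    paste("chr1", "toy", "CDS", 301, 320, ".", "+", "0", attr1, sep = "\t"),
    paste("chr1", "toy", "transcript", 501, 600, ".", "-", ".", attr2,
          sep = "\t"),
    paste("chr1", "toy", "exon", 501, 600, ".", "-", ".", attr2, sep = "\t"),
    paste("chr1", "toy", "CDS", 521, 580, ".", "-", "0", attr2, sep = "\t"),
    paste("chr1", "toy", "transcript", 330, 400, ".", "+", ".", attr3,
          sep = "\t"),
    paste("chr1", "toy", "exon", 330, 340, ".", "+", ".", attr3, sep = "\t"),
    paste("chr1", "toy", "exon", 390, 400, ".", "+", ".", attr3, sep = "\t"),
    paste("chr1", "toy", "CDS", 330, 340, ".", "+", "0", attr3, sep = "\t")
  ), ".gtf")
}
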