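# Gene assignment of the upstream anchor: a built-in exhaustive ungapped
# mapper for toy references, import of external SAM/BAM alignments for real
# genomes, genomic feature classification and TTS-relative positions of the
# inferred cleavage sites.

.FEATURE_PRIORITY <- c("3'UTR", "CDS", "5'UTR", "intron")

#' Read a FASTA reference
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- vapply(strsplit(names(ref), "[ \t]"), `[[`, "", 1L)
  ref
}

.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) return(read_reference(reference))
  if (is.character(reference)) return(Biostrings::DNAStringSet(reference))
  if (methods::is(reference, "DNAStringSet")) return(reference)
  stop("reference must be a DNAStringSet, a named character vector, ",
       "or a FASTA path")
}

#' Map an anchor sequence to a small reference
#'
#' Exhaustive ungapped mapping of the upstream anchor: every locus on
#' either strand with at most `map_max_mm` mismatches is found
#' (`Biostrings` fuzzy matching; equivalent to a naive all-positions
#' Hamming scan). A single locus at the minimum mismatch count is unique;
#' two or more are multimapped. Anchors shorter than `min_anchor_map_len`
#' are not mapped. Intended for toy references; real spliced alignment is
#' delegated to [read_alignments()] / [import_alignments()].
#'
#' @param anchor Anchor sequence (read orientation, i.e. transcript sense).
#' @param reference A [Biostrings::DNAStringSet], named character vector,
#'   or FASTA path. Total length must not exceed 10 Mb.
#' @param params A [pa_params()] object.
#' @return List with `status` (`"unique"`, `"multimapped"`, `"unmapped"`,
#'   `"anchor_too_short"`), and for unique hits `chrom`, `strand`, `start`,
#'   `end` (1-based reference coordinates of the aligned anchor),
#'   `cleavage_pos` (genomic coordinate of the anchor's 3'-most aligned
#'   base, the inferred cleavage/polyadenylation position) and `n_mm`.
#' @export
map_anchor_builtin <- function(anchor, reference, params = pa_params()) {
  ref <- .as_reference(reference)
  if (sum(as.numeric(Biostrings::width(ref))) > 10e6)
    stop("reference exceeds the 10 Mb guard of the built-in mapper; ",
         "align externally and use import_alignments()")
  empty <- list(status = "unmapped", chrom = NA_character_,
                strand = NA_character_, start = NA_integer_,
                end = NA_integer_, cleavage_pos = NA_integer_,
                n_mm = NA_integer_)
  anchor <- toupper(anchor)
  if (nchar(anchor) < params$min_anchor_map_len) {
    empty$status <- "anchor_too_short"
    return(empty)
  }
  pats <- list(`+` = Biostrings::DNAString(anchor),
               `-` = Biostrings::reverseComplement(
                 Biostrings::DNAString(anchor)))
  hits <- list()
  for (strand in names(pats)) {
    for (k in seq_along(ref)) {
      m <- Biostrings::matchPattern(pats[[strand]], ref[[k]],
                                    max.mismatch = params$map_max_mm)
      if (!length(m)) next
      st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
      inb <- st >= 1L & en <= length(ref[[k]])
      if (!any(inb)) next
      st <- st[inb]; en <- en[inb]
      mm <- Biostrings::neditStartingAt(pats[[strand]], ref[[k]],
                                        starting.at = st)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = names(ref)[k], strand = strand, start = st, end = en,
        n_mm = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  best <- hits[hits$n_mm == min(hits$n_mm), , drop = FALSE]
  if (nrow(best) > 1L) {
    empty$status <- "multimapped"
    return(empty)
  }
  list(status = "unique", chrom = best$chrom, strand = best$strand,
       start = best$start, end = best$end,
       cleavage_pos = if (best$strand == "-") best$start else best$end,
       n_mm = best$n_mm)
}

.assignment_frame <- function(read_id, status) {
  data.frame(read_id = read_id, status = status, chrom = NA_character_,
             strand = NA_character_, cleavage_pos = NA_integer_,
             n_mm = NA_integer_, stringsAsFactors = FALSE)
}

#' Map the anchors of a call table with the built-in mapper
#'
#' Runs [map_anchor_builtin()] on every retained call.
#'
#' @param calls A `pa_calls` data frame.
#' @param reference See [map_anchor_builtin()].
#' @param params A [pa_params()] object.
#' @return Data frame with one row per retained call: `read_id`, `status`,
#'   `chrom`, `strand`, `cleavage_pos`, `n_mm`.
#' @export
map_anchors <- function(calls, reference, params = pa_params()) {
  ref <- .as_reference(reference)
  kept <- calls[calls$discard_reason == "none", , drop = FALSE]
  out <- .assignment_frame(kept$read_id, rep("unmapped", nrow(kept)))
  for (i in seq_len(nrow(kept))) {
    h <- map_anchor_builtin(kept$anchor_seq[i], ref, params)
    out$status[i] <- h$status
    out$chrom[i] <- h$chrom
    out$strand[i] <- h$strand
    out$cleavage_pos[i] <- h$cleavage_pos
    out$n_mm[i] <- h$n_mm
  }
  out
}

#' Derive mapping statuses from external alignments
#'
#' A read is unique when it has exactly one primary mapped alignment and no
#' secondary records; reads with several primary or any secondary records
#' are multimapped; reads absent from the alignments (counted in a warning)
#' or unmapped in them are unmapped. Anchors shorter than
#' `min_anchor_map_len` are reported as `anchor_too_short` regardless of
#' the alignment content.
#'
#' @param calls A `pa_calls` data frame.
#' @param alignments Data frame from [read_alignments()].
#' @param params A [pa_params()] object.
#' @return Data frame as for [map_anchors()].
#' @export
import_alignments <- function(calls, alignments, params = pa_params()) {
  kept <- calls[calls$discard_reason == "none", , drop = FALSE]
  out <- .assignment_frame(kept$read_id, rep("unmapped", nrow(kept)))
  aln <- split(alignments, alignments$read_id)
  n_missing <- 0L
  for (i in seq_len(nrow(kept))) {
    if (!is.na(kept$anchor_len[i]) &&
        kept$anchor_len[i] < params$min_anchor_map_len) {
      out$status[i] <- "anchor_too_short"
      next
    }
    a <- aln[[kept$read_id[i]]]
    if (is.null(a)) { n_missing <- n_missing + 1L; next }
    prim <- a[a$mapped & !a$secondary & !a$supplementary, , drop = FALSE]
    n_sec <- sum(a$secondary)
    if (nrow(prim) == 1L && n_sec == 0L) {
      out$status[i] <- "unique"
      out$chrom[i] <- prim$chrom
      out$strand[i] <- prim$strand
      out$cleavage_pos[i] <- if (prim$strand == "-") prim$pos else prim$end
      out$n_mm[i] <- prim$edit_distance
    } else if (nrow(prim) + n_sec >= 2L) {
      out$status[i] <- "multimapped"
    }
  }
  if (n_missing > 0L)
    warning(n_missing, " retained read(s) absent from the alignments; ",
            "reported as unmapped")
  out
}

#' Classify a genomic position by feature context
#'
#' The position is classified against all overlapping same-strand
#' transcript features with priority 3'UTR > CDS > 5'UTR > intron;
#' positions outside every feature are intergenic.
#'
#' @param chrom,pos,strand Vectors describing the positions (recycled).
#' @param annotation A `pa_annotation` object.
#' @return Character vector of feature labels.
#' @export
assign_feature <- function(chrom, pos, strand, annotation) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  out <- rep("intergenic", n)
  ok <- !is.na(chrom) & !is.na(pos)
  if (!any(ok)) return(out)
  q <- GenomicRanges::GRanges(chrom[ok], IRanges::IRanges(pos[ok], pos[ok]),
                              strand = strand[ok])
  ov <- GenomicRanges::findOverlaps(q, annotation$features)
  if (length(ov)) {
    feat <- annotation$features$feature[S4Vectors::subjectHits(ov)]
    rank <- match(feat, .FEATURE_PRIORITY)
    best <- tapply(rank, S4Vectors::queryHits(ov), min)
    idx <- which(ok)[as.integer(names(best))]
    out[idx] <- .FEATURE_PRIORITY[as.integer(best)]
  }
  out
}

#' Assign mapped reads to genes and features
#'
#' Adds `gene_id` (the same-strand gene overlapping the cleavage position;
#' only for uniquely mapped reads) and `feature` columns to an assignment
#' table.
#'
#' @param assignments Data frame from [map_anchors()] or
#'   [import_alignments()].
#' @param annotation A `pa_annotation` object.
#' @return The assignment table with `gene_id` and `feature` columns.
#' @export
assign_genes <- function(assignments, annotation) {
  assignments$gene_id <- NA_character_
  assignments$feature <- NA_character_
  uq <- which(assignments$status == "unique")
  if (length(uq)) {
    g <- annotation$genes
    genes_gr <- GenomicRanges::GRanges(g$chrom,
                                       IRanges::IRanges(g$start, g$end),
                                       strand = g$strand)
    q <- GenomicRanges::GRanges(assignments$chrom[uq],
                                IRanges::IRanges(assignments$cleavage_pos[uq],
                                                 assignments$cleavage_pos[uq]),
                                strand = assignments$strand[uq])
    ov <- GenomicRanges::findOverlaps(q, genes_gr, select = "first")
    assignments$gene_id[uq] <- ifelse(is.na(ov), NA_character_,
                                      g$gene_id[ov])
    assignments$feature[uq] <- assign_feature(
      assignments$chrom[uq], assignments$cleavage_pos[uq],
      assignments$strand[uq], annotation)
  }
  assignments
}

#' Strand-aware distance from cleavage positions to the nearest TTS
#'
#' Signed distance (negative = upstream of the TTS in transcript
#' orientation) from each uniquely assigned cleavage position to the
#' nearest annotated TTS of its assigned gene. Reads on excluded
#' chromosomes (mitochondrial by default) and reads without a unique gene
#' get `NA`.
#'
#' @param assignments Output of [assign_genes()].
#' @param annotation A `pa_annotation` object.
#' @param exclude_chroms Chromosome names excluded from the analysis.
#' @return Integer vector of signed distances, one per assignment row.
#' @export
tts_distance <- function(assignments, annotation,
                         exclude_chroms = c("chrM", "MT")) {
  tts_by_gene <- split(annotation$transcripts$tts,
                       annotation$transcripts$gene_id)
  n <- nrow(assignments)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(assignments$gene_id[i])) next
    if (assignments$chrom[i] %in% exclude_chroms) next
    tts <- tts_by_gene[[assignments$gene_id[i]]]
    if (is.null(tts)) next
    pos <- assignments$cleavage_pos[i]
    d <- pos - tts
    if (assignments$strand[i] == "-") d <- -d
    out[i] <- d[which.min(abs(d))]
  }
  out
}
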