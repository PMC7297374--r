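# Gene annotation model: parses GTF/GFF3 via rtracklayer and derives the
# per-transcript feature geometry the caller needs -- 5'UTR / CDS / 3'UTR /
# intron intervals and the transcript termination site (TTS), the annotated
# proxy of the cleavage/polyadenylation site.

.first_or_na <- function(x) {
  vapply(x, function(v) if (length(v)) as.character(v[1L]) else NA_character_,
         character(1))
}

.strip_prefix <- function(x) sub("^(transcript|mRNA|gene):", "", x)

#' Read a GTF/GFF3 annotation into an annotation model
#'
#' Parses gene/transcript/exon/CDS features. UTRs are taken from the file
#' when present and otherwise derived as the exonic sequence outside the
#' CDS, split by position relative to the CDS on the coding strand; introns
#' are the transcript span minus the exons. The TTS of a transcript is its
#' 3'-most coordinate on its strand (the lowest coordinate on the minus
#' strand). Transcripts without exons are skipped with a warning.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A `pa_annotation` object: list with `genes` (data frame:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`), `transcripts`
#'   (`tx_id`, `gene_id`, `chrom`, `strand`, `start`, `end`, `tts`) and
#'   `features` (a [GenomicRanges::GRanges] with metadata columns
#'   `feature` in `{"5'UTR","CDS","3'UTR","intron"}`, `tx_id`, `gene_id`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  type <- tolower(as.character(gr$type))
  type[type == "mrna"] <- "transcript"
  type[type %in% c("5utr", "five_prime_utr", "utr5")] <- "five_prime_utr"
  type[type %in% c("3utr", "three_prime_utr", "utr3")] <- "three_prime_utr"

  mc <- S4Vectors::mcols(gr)
  tx_id <- if ("transcript_id" %in% names(mc)) as.character(gr$transcript_id)
           else rep(NA_character_, length(gr))
  if ("Parent" %in% names(mc)) {
    parent <- .strip_prefix(.first_or_na(gr$Parent))
    tx_id[is.na(tx_id) & type %in% c("exon", "cds", "five_prime_utr",
                                     "three_prime_utr")] <-
      parent[is.na(tx_id) & type %in% c("exon", "cds", "five_prime_utr",
                                        "three_prime_utr")]
  }
  if ("ID" %in% names(mc)) {
    id <- .strip_prefix(.first_or_na(gr$ID))
    tx_id[is.na(tx_id) & type == "transcript"] <-
      id[is.na(tx_id) & type == "transcript"]
  }
  gene_id <- if ("gene_id" %in% names(mc)) as.character(gr$gene_id)
             else rep(NA_character_, length(gr))
  if (any(is.na(gene_id)) && "Parent" %in% names(mc)) {
    parent <- .strip_prefix(.first_or_na(gr$Parent))
    gene_id[is.na(gene_id) & type == "transcript"] <-
      parent[is.na(gene_id) & type == "transcript"]
  }

  keep <- type %in% c("exon", "cds", "transcript", "five_prime_utr",
                      "three_prime_utr")
  txs <- unique(stats::na.omit(tx_id[keep]))
  if (!length(txs)) stop("no transcript features found in ", path)

  # gene of each transcript: first non-NA gene_id among its rows
  tx_gene <- vapply(txs, function(tx) {
    g <- gene_id[!is.na(tx_id) & tx_id == tx]
    g <- g[!is.na(g)]
    if (length(g)) g[1L] else tx
  }, character(1))

  feat_list <- list()
  tx_rows <- list()
  for (tx in txs) {
    sel <- !is.na(tx_id) & tx_id == tx
    ex <- gr[sel & type == "exon"]
    if (!length(ex)) {
      warning("transcript ", tx, " has no exons; skipped")
      next
    }
    ex <- GenomicRanges::reduce(ex)
    strand <- as.character(GenomicRanges::strand(ex))[1L]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    span <- range(ex)
    tts <- if (strand == "-") min(GenomicRanges::start(ex))
           else max(GenomicRanges::end(ex))
    cds <- GenomicRanges::reduce(gr[sel & type == "cds"])
    u5 <- GenomicRanges::reduce(gr[sel & type == "five_prime_utr"])
    u3 <- GenomicRanges::reduce(gr[sel & type == "three_prime_utr"])
    if (length(cds) && !length(u5) && !length(u3)) {
      utr <- GenomicRanges::setdiff(ex, cds, ignore.strand = TRUE)
      cds_lo <- min(GenomicRanges::start(cds))
      cds_hi <- max(GenomicRanges::end(cds))
      up <- utr[GenomicRanges::end(utr) < cds_lo]
      dn <- utr[GenomicRanges::start(utr) > cds_hi]
      if (strand == "-") { u5 <- dn; u3 <- up } else { u5 <- up; u3 <- dn }
    }
    introns <- GenomicRanges::setdiff(span, ex, ignore.strand = TRUE)
    add <- function(ranges, label) {
      if (!length(ranges)) return(NULL)
      GenomicRanges::GRanges(chrom, IRanges::ranges(ranges), strand,
                             feature = label, tx_id = tx,
                             gene_id = tx_gene[[tx]])
    }
    parts <- Filter(Negate(is.null),
                    list(add(u5, "5'UTR"), add(cds, "CDS"),
                         add(u3, "3'UTR"), add(introns, "intron")))
    feat_list[[tx]] <- if (length(parts)) do.call(c, parts) else NULL
    tx_rows[[tx]] <- data.frame(
      tx_id = tx, gene_id = tx_gene[[tx]], chrom = chrom, strand = strand,
      start = GenomicRanges::start(span), end = GenomicRanges::end(span),
      tts = tts, stringsAsFactors = FALSE)
  }
  if (!length(tx_rows)) stop("no usable transcripts in ", path)
  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- NULL
  features <- do.call(c, unname(feat_list[!vapply(feat_list, is.null,
                                                  logical(1))]))
  genes <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id),
    function(d) data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
                           strand = d$strand[1L], start = min(d$start),
                           end = max(d$end), stringsAsFactors = FALSE)))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = transcripts,
                 features = features),
            class = "pa_annotation")
}

#' @export
print.pa_annotation <- function(x, ...) {
  cat("pa_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", length(x$features), "feature intervals\n")
  invisible(x)
}
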