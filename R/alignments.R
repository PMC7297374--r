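# SAM/BAM import: supplies externally produced anchor alignments to the
# uniqueness filter. SAM input is converted with Rsamtools::asBam on the fly
# so that plain-text alignments can be used directly.

#' Read alignments from a SAM or BAM file
#'
#' Yields one row per alignment record. Secondary (flag 0x100) and
#' supplementary (flag 0x800) records are flagged as such; unmapped records
#' are kept with an `NA` locus. A file without a header is rejected.
#'
#' @param path Path to a SAM or BAM file (SAM detected by extension).
#' @return Data frame with columns `read_id`, `chrom`, `pos` (1-based
#'   leftmost), `end` (reference end, from the CIGAR), `strand`,
#'   `mapped`, `secondary`, `supplementary`, `edit_distance` (NM tag, `NA`
#'   when absent).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    first <- readLines(path, n = 1L)
    if (!length(first) || !startsWith(first, "@"))
      stop("SAM file ", path, " has no header")
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to parse SAM file ", path,
                               " (missing header?): ", conditionMessage(e)))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar"),
    tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  width <- rep(NA_integer_, length(flag))
  has_cigar <- mapped & !is.na(res$cigar)
  if (any(has_cigar))
    width[has_cigar] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      res$cigar[has_cigar])
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  data.frame(
    read_id = res$qname,
    chrom = ifelse(mapped, as.character(res$rname), NA_character_),
    pos = ifelse(mapped, res$pos, NA_integer_),
    end = ifelse(mapped, res$pos + width - 1L, NA_integer_),
    strand = ifelse(mapped, as.character(res$strand), NA_character_),
    mapped = mapped,
    secondary = bitwAnd(flag, 256L) != 0L,
    supplementary = bitwAnd(flag, 2048L) != 0L,
    edit_distance = as.integer(nm),
    stringsAsFactors = FALSE)
}
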