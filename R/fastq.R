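# FASTQ reading/writing. Records are parsed directly over readLines so that
# malformed records can be reported by record number and reading can stop at
# `limit` records; quality is Sanger Phred+33 only.

.is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual Quality string (one character per base).
#' @return `phred_scores()`: integer vector of Phred scores.
#' @export
phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' @rdname phred_scores
#' @param scores Integer vector of Phred scores.
#' @return `phred_string()`: the encoded quality string.
#' @export
phred_string <- function(scores) intToUtf8(scores + 33L)

#' Read a FASTQ file
#'
#' Reads plain or gzipped FASTQ (4-line records; gzip is detected from the
#' file's magic bytes). Qualities must be Sanger Phred+33; scores above 60
#' are rejected as a likely Phred+64 file rather than silently re-scaled.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param limit Optional maximum number of records to read.
#' @return A `pa_reads` data frame with columns `read_id` (the header token
#'   before the first whitespace, without `@`), `bases` (uppercase) and
#'   `qual` (Phred+33 string).
#' @export
read_fastq <- function(path, limit = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (.is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  n_lines <- if (is.null(limit)) -1L else 4L * as.integer(limit)
  lines <- readLines(con, n = n_lines)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(structure(data.frame(read_id = character(), bases = character(),
                                qual = character(), stringsAsFactors = FALSE),
                     class = c("pa_reads", "data.frame")))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  bases <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": missing '@' or '+' line")
  bad <- which(nchar(bases) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": sequence and quality lengths differ")
  bad <- which(grepl("[^ACGTN]", bases))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": bases outside {A,C,G,T,N}")
  allq <- utf8ToInt(paste(qual, collapse = "")) - 33L
  if (length(allq) && (min(allq) < 0L || max(allq) > 60L))
    stop("quality scores outside [0, 60] in ", path,
         "; only Sanger Phred+33 encoding is supported")
  read_id <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[[`, "", 1L))
  structure(data.frame(read_id = read_id, bases = bases, qual = qual,
                       stringsAsFactors = FALSE),
            class = c("pa_reads", "data.frame"))
}

#' Write a FASTQ file
#'
#' @param reads Data frame with columns `read_id`, `bases`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases", "qual") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                           "+", reads$qual))
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
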