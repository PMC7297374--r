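# Tab-separated call and profile tables. Deterministic column and row order
# (sorted by read_id / gene_id), lossless round-trips, no timestamps.

.CALL_COLS <- c("read_id", "gene_id", "prelim_start", "prelim_end",
                "tail_start", "tail_end", "tail_len", "adaptor_found",
                "qc_truncated", "discard_reason", "anchor_seq", "anchor_len")

#' Write / read a tail-call table
#'
#' Tab-separated with one header line; rows sorted by `read_id` so repeated
#' writes of the same table are byte-identical. A missing `gene_id` column
#' (calls not yet assigned to genes) is written as `NA`.
#'
#' @param calls A `pa_calls` data frame (see [call_tails()]).
#' @param path Output path.
#' @return `write_calls()`: `path` invisibly; `read_calls()`: the table.
#' @export
write_calls <- function(calls, path) {
  if (is.null(calls$gene_id))
    calls$gene_id <- rep(NA_character_, nrow(calls))
  missing <- setdiff(.CALL_COLS, names(calls))
  if (length(missing)) stop("calls table lacks columns: ",
                            paste(missing, collapse = ", "))
  calls <- calls[order(calls$read_id), .CALL_COLS, drop = FALSE]
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    read_id = "character", gene_id = "character",
    prelim_start = "integer", prelim_end = "integer",
    tail_start = "integer", tail_end = "integer", tail_len = "integer",
    adaptor_found = "logical", qc_truncated = "logical",
    discard_reason = "character", anchor_seq = "character",
    anchor_len = "integer"))
  class(out) <- c("pa_calls", "data.frame")
  out
}

#' Write / read a per-gene tail profile table
#'
#' Tab-separated `gene_id`, `n_reads`, `median_tail_len`, sorted by
#' `gene_id`.
#'
#' @param profiles Data frame as returned by [gene_medians()].
#' @param path Output path.
#' @return `write_gene_profiles()`: `path` invisibly;
#'   `read_gene_profiles()`: the table.
#' @export
write_gene_profiles <- function(profiles, path) {
  cols <- c("gene_id", "n_reads", "median_tail_len")
  missing <- setdiff(cols, names(profiles))
  if (length(missing)) stop("profile table lacks columns: ",
                            paste(missing, collapse = ", "))
  profiles <- profiles[order(profiles$gene_id), cols, drop = FALSE]
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_gene_profiles
#' @export
read_gene_profiles <- function(path) {
  if (!file.exists(path)) stop("profiles file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    gene_id = "character", n_reads = "integer",
    median_tail_len = "integer"))
}
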