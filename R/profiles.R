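# Aggregate statistics: per-gene medians, tail-length histograms, per-cycle
# and junction-anchored base composition, empirical cumulative fractions,
# adaptor-detection error-rate sweeps and cross-sample concordance.

# lower median: for even counts the lower of the two central values, so the
# statistic is always an observed (integer) tail length
.lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1L) / 2L)]
}

.retained <- function(calls) calls[calls$discard_reason == "none" &
                                   !is.na(calls$tail_len), , drop = FALSE]

.BASES <- c("A", "C", "G", "T", "N")

# per-column base fractions of a set of aligned character strings; offsets
# gives the column labels. Strings shorter than a column simply do not
# cover it.
.composition <- function(strings, max_len, labels = seq_len(max_len)) {
  counts <- matrix(0, nrow = length(.BASES), ncol = max_len,
                   dimnames = list(.BASES, labels))
  if (length(strings)) {
    nc <- nchar(strings)
    for (j in seq_len(max_len)) {
      b <- substr(strings[nc >= j], j, j)
      if (!length(b)) next
      t <- table(factor(b, levels = .BASES))
      counts[, j] <- as.numeric(t)
    }
  }
  cov <- colSums(counts)
  frac <- sweep(counts, 2L, ifelse(cov > 0, cov, 1), "/")
  structure(list(fraction = frac, coverage = cov, labels = labels),
            class = "pa_composition")
}

#' @export
print.pa_composition <- function(x, ...) {
  cat("pa_composition:", ncol(x$fraction), "columns; coverage",
      min(x$coverage), "-", max(x$coverage), "reads\n")
  invisible(x)
}

#' Per-gene median tail lengths
#'
#' Aggregates retained, uniquely gene-assigned reads into per-gene tail
#' profiles. The median uses the lower-median convention (for even counts
#' the lower of the two central values), so the reported value is always an
#' observed integer tail length. Genes without reads are absent.
#'
#' @param calls A `pa_calls` data frame.
#' @param assignments Output of [assign_genes()]; only rows with
#'   `status == "unique"` and a non-`NA` `gene_id` contribute. Pass `NULL`
#'   if `calls` already carries a `gene_id` column.
#' @return Data frame `gene_id`, `n_reads`, `median_tail_len`, sorted by
#'   `gene_id`, with the pooled sample median of all contributing reads in
#'   attribute `"sample_median"`.
#' @export
gene_medians <- function(calls, assignments = NULL) {
  kept <- .retained(calls)
  if (!is.null(assignments)) {
    uq <- assignments[assignments$status == "unique" &
                      !is.na(assignments$gene_id), c("read_id", "gene_id")]
    kept$gene_id <- NULL
    kept <- merge(kept, uq, by = "read_id")
  }
  if (is.null(kept$gene_id)) stop("no gene assignments available")
  kept <- kept[!is.na(kept$gene_id), , drop = FALSE]
  sp <- split(kept$tail_len, kept$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_reads = vapply(sp, length, integer(1)),
    median_tail_len = vapply(sp, .lower_median, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_median") <- if (nrow(kept)) .lower_median(kept$tail_len)
                                else NA_integer_
  out
}

#' Pooled sample median tail length
#'
#' Lower median of the tail lengths of all retained reads, irrespective of
#' gene assignment.
#'
#' @param calls A `pa_calls` data frame.
#' @return Integer scalar (`NA` if no read is retained).
#' @export
sample_median <- function(calls) {
  kept <- .retained(calls)
  if (!nrow(kept)) return(NA_integer_)
  .lower_median(kept$tail_len)
}

#' Tail-length histogram
#'
#' Counts retained tail lengths into half-open bins `[k*w, (k+1)*w)`.
#'
#' @param tail_lengths Integer vector of tail lengths (or a `pa_calls`
#'   data frame, from which retained tails are taken).
#' @param bin_width Bin width in nt (>= 1).
#' @return Data frame `bin_start`, `bin_end`, `count`, `fraction`;
#'   fractions sum to 1.
#' @export
tail_histogram <- function(tail_lengths, bin_width = 5L) {
  if (is.data.frame(tail_lengths)) tail_lengths <- .retained(tail_lengths)$tail_len
  stopifnot(bin_width >= 1L, length(tail_lengths) >= 1L)
  k <- tail_lengths %/% bin_width
  t <- table(factor(k, levels = 0:max(k)))
  data.frame(bin_start = as.integer(names(t)) * bin_width,
             bin_end = (as.integer(names(t)) + 1L) * bin_width,
             count = as.integer(t),
             fraction = as.integer(t) / length(tail_lengths))
}

#' Base composition per sequencing cycle
#'
#' Fraction of each base among the reads covering each cycle; the
#' characteristic rise of the A fraction marks the poly(A) region and, on
#' two-channel instruments, a late G rise marks signal loss.
#'
#' @param reads Data frame with a `bases` column.
#' @return A `pa_composition` object: `fraction` (5 x cycles matrix over
#'   A/C/G/T/N; every covered column sums to 1), `coverage` (reads per
#'   cycle), `labels` (cycle numbers).
#' @export
base_composition_by_cycle <- function(reads) {
  .composition(reads$bases, max(nchar(reads$bases)))
}

#' Base composition around the tail/adaptor junction
#'
#' Aligns retained reads at their called tail end and reports per-offset
#' base composition for the last `upstream` tail bases (offsets
#' `-upstream..-1`) and the first `downstream` post-tail bases (offsets
#' `0..downstream-1`; offset 0 is the first base after the tail). The decay
#' of the A fraction over non-negative offsets quantifies homopolymer
#' signal bleeding into the adaptor.
#'
#' @param calls A `pa_calls` data frame.
#' @param reads The read table the calls were made from.
#' @param upstream,downstream Number of tail / post-tail positions.
#' @return A `pa_composition` object with offset labels.
#' @export
junction_composition <- function(calls, reads, upstream = 10L,
                                 downstream = 30L) {
  kept <- .retained(calls)
  m <- merge(kept, reads[, c("read_id", "bases")], by = "read_id")
  # re-anchor every read so that column upstream+1 is the first post-tail base
  windows <- substr(m$bases,
                    pmax(m$tail_end - upstream + 1L, 1L),
                    nchar(m$bases))
  # left-pad reads whose tail starts within `upstream` of the read start
  pad <- pmax(upstream - m$tail_end, 0L)
  windows <- paste0(strrep("N", pad), windows)
  comp <- .composition(windows, upstream + downstream,
                       labels = c(-(upstream:1), 0:(downstream - 1L)))
  comp
}

#' Empirical cumulative fraction of tail lengths
#'
#' Right-continuous empirical CDF of retained tail lengths: the fraction of
#' reads with tail length <= x, evaluated at each observed length.
#'
#' @param tail_lengths Integer vector (or `pa_calls` data frame).
#' @return Data frame `tail_len`, `cum_fraction` (nondecreasing, ends at 1).
#' @export
cumulative_fraction <- function(tail_lengths) {
  if (is.data.frame(tail_lengths)) tail_lengths <- .retained(tail_lengths)$tail_len
  stopifnot(length(tail_lengths) >= 1L)
  x <- sort(unique(tail_lengths))
  data.frame(tail_len = x, cum_fraction = stats::ecdf(tail_lengths)(x))
}

#' Adaptor detection across error rates
#'
#' Re-runs [detect_adaptor()] on every retained read at each error rate and
#' reports the detected fraction. The default denominator is all retained
#' tail reads (a tail running to the read end counts as not detected,
#' mirroring the lower adaptor recovery of long tails);
#' `eligible_only = TRUE` restricts the denominator to reads with at least
#' a full probe length downstream of the tail.
#'
#' @param calls A `pa_calls` data frame.
#' @param reads The read table the calls were made from.
#' @param adaptor3 3'-adaptor sequence.
#' @param rates Ascending error rates to sweep.
#' @param eligible_only Restrict the denominator (see above).
#' @param params A [pa_params()] object.
#' @return Data frame `error_rate`, `n`, `n_detected`, `fraction`;
#'   `fraction` is nondecreasing in `error_rate`.
#' @export
adaptor_detection_sweep <- function(calls, reads, adaptor3,
                                    rates = c(0.1, 0.2, 0.25, 0.3, 0.35),
                                    eligible_only = FALSE,
                                    params = pa_params()) {
  stopifnot(!is.unsorted(rates))
  kept <- .retained(calls)
  m <- merge(kept, reads[, c("read_id", "bases")], by = "read_id")
  if (eligible_only)
    m <- m[nchar(m$bases) - m$tail_end >= params$adaptor_probe_len, ,
           drop = FALSE]
  probe <- charToRaw(substr(toupper(adaptor3), 1L, params$adaptor_probe_len))
  out <- data.frame(error_rate = rates, n = nrow(m), n_detected = 0L,
                    fraction = 0)
  if (!nrow(m)) return(out)
  braws <- lapply(m$bases, charToRaw)
  for (r in seq_along(rates)) {
    det <- mapply(function(b, e) .detect_adaptor(b, e, probe, rates[r],
                                                 params),
                  braws, m$tail_end)
    out$n_detected[r] <- sum(det)
    out$fraction[r] <- mean(det)
  }
  out
}

#' Cross-sample concordance of per-gene medians
#'
#' Inner-joins two per-gene profile tables on `gene_id` and reports Pearson
#' and Spearman correlations of the median tail lengths.
#'
#' @param profiles_a,profiles_b Data frames from [gene_medians()].
#' @return List with `table` (gene_id, median_a, median_b), `n_genes`,
#'   `pearson`, `spearman`, `mean_difference` (b - a).
#' @export
median_concordance <- function(profiles_a, profiles_b) {
  m <- merge(profiles_a[, c("gene_id", "median_tail_len")],
             profiles_b[, c("gene_id", "median_tail_len")],
             by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L)
    stop("fewer than 3 shared genes between the two profiles")
  names(m) <- c("gene_id", "median_a", "median_b")
  list(table = m, n_genes = nrow(m),
       pearson = stats::cor(m$median_a, m$median_b, method = "pearson"),
       spearman = stats::cor(m$median_a, m$median_b, method = "spearman"),
       mean_difference = mean(m$median_b - m$median_a))
}
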