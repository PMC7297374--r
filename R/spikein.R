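# Spike-in handling: the two printed poly(A)-length standards (40-nt and
# 120-nt tails behind construct-specific 5' adaptors transcribed from a T7
# promoter), retrieval of their reads by fuzzy 5'-adaptor matching, and
# tail profiles per spike-in.

.T7_PROMOTER <- "TAATACGACTCACTATAGGG"

#' Define a spike-in standard
#'
#' A spike-in is identified by its construct-specific 5' adaptor. The
#' transcribed adaptor -- the part present in reads -- is the printed
#' adaptor with the 20-nt T7 promoter removed (transcription starts at the
#' promoter's final G triplet, which stays in the transcript as part of the
#' removed promoter accounting; both printed constructs leave a 40-nt
#' transcribed adaptor).
#'
#' @param name Spike-in label, e.g. `"A40"`.
#' @param full_5prime_adaptor Printed 5'-adaptor DNA including the T7
#'   promoter prefix.
#' @param expected_tail_len True poly(A) tail length of the construct (nt).
#' @param t7_promoter Promoter prefix removed from the transcript.
#' @param library_prefix_len Number of library bases (non-templated Gs from
#'   template switching) preceding the adaptor in a read.
#' @return A `pa_spikein` object.
#' @export
spikein_spec <- function(name, full_5prime_adaptor, expected_tail_len,
                         t7_promoter = .T7_PROMOTER,
                         library_prefix_len = 6L) {
  full_5prime_adaptor <- toupper(full_5prime_adaptor)
  if (!startsWith(full_5prime_adaptor, t7_promoter))
    stop("5' adaptor of ", name, " does not start with the T7 promoter")
  expected_tail_len <- as.integer(expected_tail_len)
  if (expected_tail_len <= 0L) stop("expected_tail_len must be positive")
  structure(list(
    name = name,
    full_5prime_adaptor = full_5prime_adaptor,
    transcribed_adaptor = substr(full_5prime_adaptor,
                                 nchar(t7_promoter) + 1L,
                                 nchar(full_5prime_adaptor)),
    expected_tail_len = expected_tail_len,
    library_prefix_len = as.integer(library_prefix_len)),
    class = "pa_spikein")
}

#' The two published spike-in standards
#'
#' A40 (40-nt tail) and A120 (120-nt tail), with their printed
#' construct-specific 5' adaptors.
#'
#' @return Named list of two `pa_spikein` objects.
#' @export
spikein_default_specs <- function() {
  list(
    A40 = spikein_spec(
      "A40", "TAATACGACTCACTATAGGGTTTAACGCGAATTAATTCTGTGGAATGTGTGTCAGTTAGG",
      40L),
    A120 = spikein_spec(
      "A120", "TAATACGACTCACTATAGGGTCGACGCTCAAGTCAGAGGTGGCGAAACCCGACAGGACTA",
      120L))
}

# smallest start position / mismatch count of spec's transcribed adaptor in
# a read, scanning the first library_prefix_len + 4 start positions
.spikein_match <- function(bases, spec, max_mm) {
  ad <- charToRaw(spec$transcribed_adaptor)
  b <- charToRaw(bases)
  al <- length(ad)
  for (s in seq_len(spec$library_prefix_len + 4L)) {
    if (s + al - 1L > length(b)) break
    mm <- sum(b[s:(s + al - 1L)] != ad)
    if (mm <= max_mm) return(list(start = s, mm = mm))
  }
  NULL
}

#' Partition reads by spike-in identity
#'
#' A read matches a spike-in when the spike-in's transcribed 5' adaptor
#' occurs with at most `max_mm` mismatches starting within the first
#' `library_prefix_len + 4` read positions. Reads matching two spike-ins
#' are counted ambiguous and left unmatched. Specs whose adaptors are not
#' mutually distinguishable (pairwise Hamming distance over the comparable
#' prefix <= 2 * `max_mm`) are rejected at configuration time.
#'
#' @param reads Read table (`read_id`, `bases`, `qual`).
#' @param specs List of `pa_spikein` objects (default: the two published
#'   standards).
#' @param max_mm Mismatch budget for adaptor retrieval.
#' @return List with `matched` (named list of read tables, one per spec,
#'   each with a `spike_match_start` column), `unmatched` (read table) and
#'   `n_ambiguous`.
#' @export
extract_spikein_reads <- function(reads, specs = spikein_default_specs(),
                                  max_mm = 2L) {
  stopifnot(length(specs) >= 1L)
  if (length(specs) > 1L) {
    for (i in seq_len(length(specs) - 1L)) for (j in (i + 1L):length(specs)) {
      a <- specs[[i]]$transcribed_adaptor; b <- specs[[j]]$transcribed_adaptor
      k <- min(nchar(a), nchar(b))
      if (.hamming(substr(a, 1, k), substr(b, 1, k)) <= 2L * max_mm)
        stop("spike-in specs ", specs[[i]]$name, " and ", specs[[j]]$name,
             " are not distinguishable at max_mm = ", max_mm)
    }
  }
  n <- nrow(reads)
  which_spec <- rep(0L, n)
  match_start <- rep(NA_integer_, n)
  n_ambiguous <- 0L
  for (i in seq_len(n)) {
    hit <- 0L
    for (k in seq_along(specs)) {
      m <- .spikein_match(reads$bases[i], specs[[k]], max_mm)
      if (!is.null(m)) {
        if (hit > 0L) { hit <- -1L; break }
        hit <- k
        match_start[i] <- m$start
      }
    }
    if (hit == -1L) { n_ambiguous <- n_ambiguous + 1L; hit <- 0L }
    which_spec[i] <- hit
  }
  matched <- lapply(seq_along(specs), function(k) {
    sub <- reads[which_spec == k, , drop = FALSE]
    sub$spike_match_start <- match_start[which_spec == k]
    rownames(sub) <- NULL
    sub
  })
  names(matched) <- vapply(specs, `[[`, "", "name")
  unmatched <- reads[which_spec == 0L, , drop = FALSE]
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched = unmatched, n_ambiguous = n_ambiguous)
}

#' Tail profile of one spike-in
#'
#' Calls tails on the reads matched to a spike-in, with the preliminary
#' 5'-anchor search constrained to start no earlier than the last base of
#' the transcribed adaptor (so a terminal adaptor adenosine may merge into
#' the tail, as it does in the published A120 accounting), and aggregates
#' the retained tails.
#'
#' @param matched_reads Read table from [extract_spikein_reads()] (with the
#'   `spike_match_start` column; reads without it are assumed to carry the
#'   adaptor at position `library_prefix_len + 1`).
#' @param spec The `pa_spikein` the reads were matched to.
#' @param adaptor3 Optional 3'-adaptor for detection and the error-rate
#'   sweep.
#' @param params A [pa_params()] object.
#' @param bin_width Histogram bin width (nt).
#' @return List with `calls`, `n_reads`, `median_tail_len`, `histogram`,
#'   `ecdf` and (when `adaptor3` is given) `adaptor_sweep`.
#' @export
spikein_profile <- function(matched_reads, spec, adaptor3 = NULL,
                            params = pa_params(), bin_width = 1L) {
  stopifnot(nrow(matched_reads) >= 1L)
  start <- matched_reads$spike_match_start
  if (is.null(start)) start <- rep(spec$library_prefix_len + 1L,
                                   nrow(matched_reads))
  min_start <- start + nchar(spec$transcribed_adaptor) - 1L
  calls <- call_tails(matched_reads, adaptor3 = adaptor3, params = params,
                      min_start = min_start)
  kept <- .retained(calls)
  out <- list(calls = calls, n_reads = nrow(kept),
              median_tail_len = if (nrow(kept)) .lower_median(kept$tail_len)
                                else NA_integer_)
  if (nrow(kept)) {
    out$histogram <- tail_histogram(kept$tail_len, bin_width)
    out$ecdf <- cumulative_fraction(kept$tail_len)
    if (!is.null(adaptor3))
      out$adaptor_sweep <- adaptor_detection_sweep(calls, matched_reads,
                                                   adaptor3, params = params)
  }
  out
}
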