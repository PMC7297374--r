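# Core poly(A) caller: trimming, preliminary anchor scan, refinement,
# quality-bleeding truncation, 3'-adaptor detection. All coordinates are
# 1-based inclusive on the trimmed read.

.RAW_A <- charToRaw("A")
.RAW_G <- charToRaw("G")

.is_a <- function(bases) charToRaw(bases) == .RAW_A

.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# sliding-window counts of non-A bases; returns integer vector indexed by
# window start (length L - w + 1), or NULL if the window does not fit
.window_mismatches <- function(isA, w) {
  L <- length(isA)
  if (L < w) return(NULL)
  cs <- cumsum(!isA)
  cs[w:L] - c(0L, cs)[seq_len(L - w + 1L)]
}

#' Trim template-switch artifacts from a read
#'
#' Removes, in order: (a) a 5'-adaptor prefix, if `adaptor5` is given and
#' matches the read prefix (after any leading non-templated G run) within
#' `adaptor_error_rate`; (b) everything from the first G run of length >=
#' `polyG_min_run` onward -- on two-channel chemistry absence of signal is
#' called G, so long G runs mark signal loss. Qualities are trimmed in
#' lockstep. 3'-adaptor bases are deliberately left in place: they are the
#' substrate of [detect_adaptor()].
#'
#' @param bases Read sequence (uppercase `A`/`C`/`G`/`T`/`N`).
#' @param qual Phred+33-encoded quality string, same length as `bases`.
#' @param adaptor5 Optional 5'-adaptor sequence to strip, or `NULL`.
#' @param params A [pa_params()] object.
#' @return List with trimmed `bases` and `qual` strings.
#' @export
trim_read <- function(bases, qual, adaptor5 = NULL, params = pa_params()) {
  stopifnot(nchar(bases) == nchar(qual))
  if (!is.null(adaptor5) && nzchar(adaptor5) && nchar(bases) > 0L) {
    r <- charToRaw(bases)
    g <- 0L
    while (g < length(r) && r[g + 1L] == .RAW_G) g <- g + 1L
    al <- nchar(adaptor5)
    if (g + al <= nchar(bases)) {
      mm <- .hamming(substr(bases, g + 1L, g + al), toupper(adaptor5))
      if (mm <= floor(params$adaptor_error_rate * al)) {
        bases <- substr(bases, g + al + 1L, nchar(bases))
        qual <- substr(qual, g + al + 1L, nchar(qual))
      }
    }
  }
  if (nchar(bases) > 0L) {
    r <- rle(as.vector(charToRaw(bases) == .RAW_G))
    bad <- which(r$values & r$lengths >= params$polyG_min_run)
    if (length(bad)) {
      cut <- sum(r$lengths[seq_len(bad[1L] - 1L)])  # keep bases 1..cut
      bases <- substr(bases, 1L, cut)
      qual <- substr(qual, 1L, cut)
    }
  }
  list(bases = bases, qual = qual)
}

# internal scan over a logical is-A vector; min_start constrains the 5'
# anchor window start (used for spike-in calling)
.find_prelim <- function(isA, p, min_start = 1L) {
  nm5 <- .window_mismatches(isA, p$anchor5_len)
  nm3 <- .window_mismatches(isA, p$anchor3_len)
  if (is.null(nm5) || is.null(nm3)) return(list(reason = "no_prelim"))
  ok5 <- which(nm5 <= p$anchor5_max_mm)
  if (min_start > 1L) ok5 <- ok5[ok5 >= min_start]
  ok3 <- which(nm3 <= p$anchor3_max_mm)
  if (!length(ok5) || !length(ok3)) return(list(reason = "no_prelim"))
  s <- ok5[1L]
  e <- ok3[length(ok3)] + p$anchor3_len - 1L
  if (e < s) return(list(reason = "no_prelim"))
  if (e - s + 1L < p$min_prelim_len) return(list(reason = "prelim_too_short"))
  list(start = s, end = e, reason = "none")
}

#' Locate the preliminary poly(A) region
#'
#' Slides a 9-nt window 5'->3'; the first window with at most
#' `anchor5_max_mm` non-A bases opens the region. Slides a 6-nt window
#' 3'->5'; the first qualifying window closest to the 3' end closes it. The
#' interval in between (window starts/ends included) is the preliminary
#' poly(A) region; regions shorter than `min_prelim_len` are rejected.
#'
#' @param bases Trimmed read sequence.
#' @param params A [pa_params()] object.
#' @param min_start Smallest allowed 5'-anchor window start (1-based);
#'   used to confine the search downstream of a known 5' adaptor.
#' @return List with `start`, `end` (1-based inclusive) and `reason`
#'   `"none"`, or only a `reason` (`"no_prelim"` / `"prelim_too_short"`)
#'   when no region is retained.
#' @export
find_preliminary_region <- function(bases, params = pa_params(),
                                    min_start = 1L) {
  if (nchar(bases) == 0L) return(list(reason = "no_prelim"))
  .find_prelim(.is_a(bases), params, as.integer(min_start))
}

# internal refinement over isA; returns list(start, end, reason) in absolute
# coordinates. Splits the preliminary region at non-A runs >= nonA_split_run,
# strips each fragment to its A-bounded core, keeps candidates containing a
# pure-A run >= min_pure_A_run (and >= min_prelim_len long), and picks the
# longest (ties -> 5'-most). Equivalent to choosing the longest subinterval
# that starts/ends on A, contains no splitting non-A run and has the pure-A
# core.
.refine <- function(isA, start, end, p) {
  v <- isA[start:end]
  r <- rle(v)
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  splitter <- !r$values & r$lengths >= p$nonA_split_run
  best <- NULL
  i <- 1L
  while (i <= n) {
    if (splitter[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && !splitter[j + 1L]) j <- j + 1L
    runs <- i:j
    a_runs <- runs[r$values[runs]]
    if (length(a_runs)) {
      s_rel <- starts[a_runs[1L]]
      e_rel <- ends[a_runs[length(a_runs)]]
      seg_len <- e_rel - s_rel + 1L
      pure <- max(r$lengths[a_runs])
      if (pure >= p$min_pure_A_run && seg_len >= p$min_prelim_len &&
          (is.null(best) || seg_len > best$len)) {
        best <- list(start = start + s_rel - 1L, end = start + e_rel - 1L,
                     len = seg_len)
      }
    }
    i <- j + 1L
  }
  if (is.null(best)) return(list(reason = "no_pure_run"))
  list(start = best$start, end = best$end, reason = "none")
}

#' Refine the preliminary region into the poly(A) tail
#'
#' Within the preliminary region, every maximal non-A run of length >=
#' `nonA_split_run` splits the region into segments. Each segment is
#' stripped to start and end on an adenosine; segments lacking a run of
#' `min_pure_A_run` consecutive adenosines (or shorter than
#' `min_prelim_len`) are rejected. Among the valid segments the longest is
#' the tail; ties go to the 5'-most. This removes genome-encoded internal
#' A stretches while tolerating isolated sequencing errors inside the tail.
#'
#' @param bases Trimmed read sequence.
#' @param prelim List or vector with elements `start`, `end` (1-based).
#' @param params A [pa_params()] object.
#' @return List with `start`, `end`, `reason = "none"`, or only
#'   `reason = "no_pure_run"`.
#' @export
refine_region <- function(bases, prelim, params = pa_params()) {
  s <- as.integer(prelim[["start"]]); e <- as.integer(prelim[["end"]])
  stopifnot(s >= 1L, e <= nchar(bases), s <= e)
  .refine(.is_a(bases), s, e, params)
}

# internal QC truncation; scores is the integer Phred vector of the whole
# read. Returns list(start, end, qc_truncated, reason).
.qc_filter <- function(isA, scores, start, end, p) {
  if (!p$qc_filter_enabled)
    return(list(start = start, end = end, qc_truncated = FALSE,
                reason = "none"))
  w <- p$qc_window
  out <- list(start = start, end = end, qc_truncated = FALSE, reason = "none")
  if (end - start + 1L >= w) {
    q <- scores[start:end]
    cs <- cumsum(q)
    sums <- cs[w:length(q)] - c(0, cs)[seq_len(length(q) - w + 1L)]
    bad <- which(sums / w < p$qc_mean_threshold)
    if (length(bad)) {
      new_end <- start + bad[1L] - 2L  # last base before the offending window
      # the tail must still end on an adenosine
      while (new_end >= start && !isA[new_end]) new_end <- new_end - 1L
      out$qc_truncated <- TRUE
      if (new_end < start) return(list(start = NA_integer_, end = NA_integer_,
                                       qc_truncated = TRUE,
                                       reason = "no_pure_run"))
      out$end <- new_end
      len <- new_end - start + 1L
      pure <- with(rle(isA[start:new_end]),
                   if (any(values)) max(lengths[values]) else 0L)
      if (len < p$min_prelim_len || pure < p$min_pure_A_run) {
        out$start <- NA_integer_; out$end <- NA_integer_
        out$reason <- "no_pure_run"
      }
    }
  }
  out
}

#' Truncate homopolymer signal bleeding by base quality
#'
#' Scans the tail 5'->3' with a window of `qc_window` consecutive positions;
#' at the first window whose mean Phred score is strictly below
#' `qc_mean_threshold` the tail is truncated just before the window (the
#' quality collapse at the tail/adaptor junction marks the true tail end,
#' and bled adenosines carry low scores). A no-op unless
#' `qc_filter_enabled` is `TRUE`. If the truncated tail violates the
#' minimum-length or pure-run constraints the read is discarded.
#'
#' The operation never lengthens the tail and is idempotent.
#'
#' @param bases Trimmed read sequence.
#' @param scores Integer Phred scores for the whole read.
#' @param tail List or vector with `start`, `end` of the called tail.
#' @param params A [pa_params()] object.
#' @return List with `start`, `end`, `qc_truncated`, `reason` (`"none"` or
#'   `"no_pure_run"`; positions are `NA` when discarded).
#' @export
apply_quality_bleed_filter <- function(bases, scores, tail,
                                       params = pa_params()) {
  s <- as.integer(tail[["start"]]); e <- as.integer(tail[["end"]])
  stopifnot(s >= 1L, e <= nchar(bases), length(scores) == nchar(bases))
  .qc_filter(.is_a(bases), scores, s, e, params)
}

# internal adaptor scan on the raw read vector
.detect_adaptor <- function(braw, tail_end, probe_raw, error_rate, p) {
  plen <- length(probe_raw)
  allowed <- floor(error_rate * plen)
  for (o in 0:p$adaptor_max_offset) {
    i1 <- tail_end + 1L + o
    i2 <- i1 + plen - 1L
    if (i2 > length(braw)) next
    if (sum(braw[i1:i2] != probe_raw) <= allowed) return(TRUE)
  }
  FALSE
}

#' Detect the 3' adaptor downstream of the tail
#'
#' Compares the first `adaptor_probe_len` bases of `adaptor3` against the
#' read at offsets `0..adaptor_max_offset` after the tail end; the adaptor
#' is detected if the Hamming distance is at most
#' `floor(error_rate * adaptor_probe_len)` at any offset. Returns `FALSE`
#' when fewer than `adaptor_probe_len` bases remain at every offset (a tail
#' running to the read end cannot have a detectable adaptor). Detection is
#' monotone in `error_rate`.
#'
#' @param bases Trimmed read sequence.
#' @param tail_end 1-based position of the last tail base.
#' @param adaptor3 3'-adaptor sequence, length >= `adaptor_probe_len`.
#' @param error_rate Tolerated mismatch fraction; defaults to
#'   `params$adaptor_error_rate`.
#' @param params A [pa_params()] object.
#' @return Logical scalar.
#' @export
detect_adaptor <- function(bases, tail_end, adaptor3,
                           error_rate = NULL, params = pa_params()) {
  if (is.null(error_rate)) error_rate <- params$adaptor_error_rate
  adaptor3 <- toupper(adaptor3)
  if (nchar(adaptor3) < params$adaptor_probe_len)
    stop("adaptor3 must be at least adaptor_probe_len (",
         params$adaptor_probe_len, ") nt long")
  probe <- charToRaw(substr(adaptor3, 1L, params$adaptor_probe_len))
  .detect_adaptor(charToRaw(bases), as.integer(tail_end), probe,
                  error_rate, params)
}

# one-read pipeline working on pre-split pieces; returns a flat named list
.call_one <- function(bases, qual, probe_raw, adaptor5, p, min_start = 1L) {
  out <- list(prelim_start = NA_integer_, prelim_end = NA_integer_,
              tail_start = NA_integer_, tail_end = NA_integer_,
              tail_len = NA_integer_, adaptor_found = FALSE,
              qc_truncated = FALSE, discard_reason = "none",
              anchor_seq = NA_character_, anchor_len = NA_integer_)
  tr <- trim_read(bases, qual, adaptor5, p)
  bases <- tr$bases; qual <- tr$qual
  if (nchar(bases) == 0L) { out$discard_reason <- "no_prelim"; return(out) }
  isA <- .is_a(bases)
  pre <- .find_prelim(isA, p, min_start)
  if (pre$reason != "none") { out$discard_reason <- pre$reason; return(out) }
  out$prelim_start <- pre$start; out$prelim_end <- pre$end
  out$anchor_seq <- substr(bases, 1L, pre$start - 1L)
  out$anchor_len <- pre$start - 1L
  tail <- .refine(isA, pre$start, pre$end, p)
  if (tail$reason != "none") { out$discard_reason <- tail$reason; return(out) }
  if (p$qc_filter_enabled) {
    scores <- utf8ToInt(qual) - 33L
    tail <- .qc_filter(isA, scores, tail$start, tail$end, p)
    out$qc_truncated <- tail$qc_truncated
    if (tail$reason != "none") {
      out$discard_reason <- tail$reason
      return(out)
    }
  }
  out$tail_start <- tail$start; out$tail_end <- tail$end
  out$tail_len <- tail$end - tail$start + 1L
  if (!is.null(probe_raw))
    out$adaptor_found <- .detect_adaptor(charToRaw(bases), tail$end,
                                         probe_raw, p$adaptor_error_rate, p)
  out
}

#' Call the poly(A) tail of a single read
#'
#' Composes [trim_read()], [find_preliminary_region()], [refine_region()],
#' [apply_quality_bleed_filter()] and [detect_adaptor()]. The sequence
#' upstream of the preliminary region is exposed as the anchor for gene
#' mapping. All failures are recorded discards, never errors.
#'
#' @param bases,qual Read sequence and Phred+33 quality string.
#' @param adaptor3 3'-adaptor sequence to scan for downstream of the tail,
#'   or `NULL` to skip detection.
#' @param adaptor5 Optional 5'-adaptor to trim, or `NULL`.
#' @param params A [pa_params()] object.
#' @param min_start Smallest allowed 5'-anchor window start (see
#'   [find_preliminary_region()]).
#' @return Named list: `prelim_start`, `prelim_end`, `tail_start`,
#'   `tail_end`, `tail_len`, `adaptor_found`, `qc_truncated`,
#'   `discard_reason` (`"none"`, `"no_prelim"`, `"prelim_too_short"`,
#'   `"no_pure_run"`), `anchor_seq`, `anchor_len`. Intervals are on the
#'   trimmed read, 1-based inclusive.
#' @export
call_read <- function(bases, qual = strrep("I", nchar(bases)),
                      adaptor3 = NULL, adaptor5 = NULL,
                      params = pa_params(), min_start = 1L) {
  probe_raw <- NULL
  if (!is.null(adaptor3)) {
    adaptor3 <- toupper(adaptor3)
    if (nchar(adaptor3) < params$adaptor_probe_len)
      stop("adaptor3 must be at least adaptor_probe_len nt long")
    probe_raw <- charToRaw(substr(adaptor3, 1L, params$adaptor_probe_len))
  }
  .call_one(toupper(bases), qual, probe_raw, adaptor5, params,
            as.integer(min_start))
}

#' Call poly(A) tails for a set of reads
#'
#' Vectorised driver of [call_read()] over a read table as returned by
#' [read_fastq()] or [simulate_reads()].
#'
#' @param reads Data frame with columns `read_id`, `bases`, `qual`.
#' @param adaptor3,adaptor5,params See [call_read()].
#' @param min_start Scalar or per-read vector of minimum 5'-anchor window
#'   starts.
#' @return A `pa_calls` data frame, one row per read, with the columns of
#'   [call_read()] plus `read_id`.
#' @examples
#' reads <- data.frame(read_id = "r1",
#'                     bases = paste0(strrep("C", 25), strrep("A", 40),
#'                                    strrep("CGT", 10)),
#'                     qual = strrep("F", 95))
#' call_tails(reads)$tail_len
#' @export
call_tails <- function(reads, adaptor3 = NULL, adaptor5 = NULL,
                       params = pa_params(), min_start = 1L) {
  stopifnot(all(c("read_id", "bases", "qual") %in% names(reads)))
  n <- nrow(reads)
  probe_raw <- NULL
  if (!is.null(adaptor3)) {
    adaptor3 <- toupper(adaptor3)
    if (nchar(adaptor3) < params$adaptor_probe_len)
      stop("adaptor3 must be at least adaptor_probe_len nt long")
    probe_raw <- charToRaw(substr(adaptor3, 1L, params$adaptor_probe_len))
  }
  min_start <- rep_len(as.integer(min_start), n)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- .call_one(reads$bases[i], reads$qual[i], probe_raw,
                          adaptor5, params, min_start[i])
  }
  pick <- function(f, w) vapply(res, `[[`, w, f)
  out <- data.frame(
    read_id = reads$read_id,
    prelim_start = pick("prelim_start", integer(1)),
    prelim_end = pick("prelim_end", integer(1)),
    tail_start = pick("tail_start", integer(1)),
    tail_end = pick("tail_end", integer(1)),
    tail_len = pick("tail_len", integer(1)),
    adaptor_found = pick("adaptor_found", logical(1)),
    qc_truncated = pick("qc_truncated", logical(1)),
    discard_reason = pick("discard_reason", character(1)),
    anchor_seq = pick("anchor_seq", character(1)),
    anchor_len = pick("anchor_len", integer(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("pa_calls", "data.frame")
  out
}
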