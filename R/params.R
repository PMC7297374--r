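#' Tail-calling parameter set
#'
#' Bundles every threshold of the poly(A) caller. Defaults reproduce the
#' published pipeline: a fuzzy 9-A anchor scanned 5'->3' and a fuzzy 6-A
#' anchor scanned 3'->5' (1 mismatch each) delimit the preliminary poly(A)
#' region; regions shorter than 10 nt are discarded; non-A runs of >= 5 nt
#' split the region and the tail must contain >= 10 consecutive adenosines;
#' anchors of >= 20 nt are mapped with <= 2 mismatches; the optional
#' quality filter truncates the tail at the first window of 3 consecutive
#' positions whose mean Phred score falls below 25.
#'
#' The anchor mismatch budgets can alternatively be given as error rates
#' (`anchor5_error_rate`, `anchor3_error_rate`); when supplied, the budget
#' is `floor(rate * anchor_len)`. Rates of 0.1 on the 9-mer and 0.2 on the
#' 6-mer floor to 0 and 1 mismatches respectively; the default is the more
#' permissive 1-mismatch budget on both anchors.
#'
#' @param anchor5_len Length of the 5' A-anchor window (nt).
#' @param anchor5_max_mm Mismatches tolerated in the 5' anchor window.
#' @param anchor3_len Length of the 3' A-anchor window (nt).
#' @param anchor3_max_mm Mismatches tolerated in the 3' anchor window.
#' @param anchor5_error_rate,anchor3_error_rate Optional error rates that
#'   override the mismatch budgets as `floor(rate * len)`.
#' @param min_prelim_len Minimum preliminary poly(A) region length (nt).
#' @param nonA_split_run Length of a consecutive non-A run that splits the
#'   preliminary region (nt).
#' @param min_pure_A_run Minimum run of consecutive adenosines a tail must
#'   contain (nt).
#' @param min_anchor_map_len Minimum upstream anchor length for mapping (nt).
#' @param map_max_mm Mismatches tolerated when mapping the anchor.
#' @param qc_window Quality-filter window size (positions).
#' @param qc_mean_threshold Mean Phred score below which a window triggers
#'   truncation (strict inequality).
#' @param qc_filter_enabled Apply the quality-bleeding filter? Off by
#'   default; intended for platforms with pronounced homopolymer signal
#'   bleeding.
#' @param adaptor_probe_len Length of the 3'-adaptor probe compared
#'   downstream of the tail (nt).
#' @param adaptor_error_rate Fraction of probe mismatches tolerated when
#'   detecting the 3' adaptor (also used for 5'-adaptor trimming).
#' @param adaptor_max_offset Maximum downstream offset at which the adaptor
#'   probe may start (nt); absorbs a few bled bases between tail and
#'   adaptor.
#' @param polyG_min_run Length of a G run treated as a dark-signal artifact
#'   and trimmed together with everything 3' of it (nt).
#'
#' @return An object of class `pa_params` (a validated named list).
#' @examples
#' p <- pa_params()
#' p$anchor5_len
#' pa_params(anchor5_error_rate = 0.1)$anchor5_max_mm  # floor(0.1 * 9) = 0
#' @export
pa_params <- function(anchor5_len = 9L, anchor5_max_mm = 1L,
                      anchor3_len = 6L, anchor3_max_mm = 1L,
                      anchor5_error_rate = NULL, anchor3_error_rate = NULL,
                      min_prelim_len = 10L, nonA_split_run = 5L,
                      min_pure_A_run = 10L,
                      min_anchor_map_len = 20L, map_max_mm = 2L,
                      qc_window = 3L, qc_mean_threshold = 25,
                      qc_filter_enabled = FALSE,
                      adaptor_probe_len = 20L, adaptor_error_rate = 0.2,
                      adaptor_max_offset = 3L,
                      polyG_min_run = 10L) {
  if (!is.null(anchor5_error_rate)) {
    stopifnot(anchor5_error_rate >= 0, anchor5_error_rate <= 1)
    anchor5_max_mm <- as.integer(floor(anchor5_error_rate * anchor5_len))
  }
  if (!is.null(anchor3_error_rate)) {
    stopifnot(anchor3_error_rate >= 0, anchor3_error_rate <= 1)
    anchor3_max_mm <- as.integer(floor(anchor3_error_rate * anchor3_len))
  }
  p <- list(anchor5_len = as.integer(anchor5_len),
            anchor5_max_mm = as.integer(anchor5_max_mm),
            anchor3_len = as.integer(anchor3_len),
            anchor3_max_mm = as.integer(anchor3_max_mm),
            min_prelim_len = as.integer(min_prelim_len),
            nonA_split_run = as.integer(nonA_split_run),
            min_pure_A_run = as.integer(min_pure_A_run),
            min_anchor_map_len = as.integer(min_anchor_map_len),
            map_max_mm = as.integer(map_max_mm),
            qc_window = as.integer(qc_window),
            qc_mean_threshold = as.numeric(qc_mean_threshold),
            qc_filter_enabled = isTRUE(qc_filter_enabled),
            adaptor_probe_len = as.integer(adaptor_probe_len),
            adaptor_error_rate = as.numeric(adaptor_error_rate),
            adaptor_max_offset = as.integer(adaptor_max_offset),
            polyG_min_run = as.integer(polyG_min_run))
  lens <- c("anchor5_len", "anchor3_len", "min_prelim_len", "nonA_split_run",
            "min_pure_A_run", "min_anchor_map_len", "qc_window",
            "adaptor_probe_len", "polyG_min_run")
  for (nm in lens)
    if (is.na(p[[nm]]) || p[[nm]] < 1L)
      stop(nm, " must be a positive integer")
  if (p$anchor5_max_mm >= p$anchor5_len)
    stop("anchor5_max_mm must be smaller than anchor5_len")
  if (p$anchor3_max_mm >= p$anchor3_len)
    stop("anchor3_max_mm must be smaller than anchor3_len")
  if (p$min_prelim_len < p$anchor3_len)
    stop("min_prelim_len must be >= anchor3_len")
  if (p$min_pure_A_run < p$anchor3_len)
    stop("min_pure_A_run must be >= anchor3_len")
  if (p$adaptor_error_rate < 0 || p$adaptor_error_rate > 1)
    stop("adaptor_error_rate must be in [0, 1]")
  if (p$map_max_mm < 0L || p$adaptor_max_offset < 0L)
    stop("map_max_mm and adaptor_max_offset must be non-negative")
  structure(p, class = "pa_params")
}

#' @export
print.pa_params <- function(x, ...) {
  cat("pa_params:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Platform presets
#'
#' Returns a `pa_params` with platform-specific defaults. All presets share
#' the published thresholds; the NovaSeq preset enables the quality-bleeding
#' filter by default (bleeding is most pronounced on that chemistry), the
#' others leave it off.
#'
#' @param platform One of `"nextseq500"`, `"hiseqx"`, `"novaseq"`.
#' @param ... Further overrides passed to [pa_params()].
#' @return A `pa_params` object.
#' @export
pa_preset <- function(platform = c("nextseq500", "hiseqx", "novaseq"), ...) {
  platform <- match.arg(platform)
  args <- list(...)
  if (platform == "novaseq" && is.null(args$qc_filter_enabled))
    args$qc_filter_enabled <- TRUE
  do.call(pa_params, args)
}
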