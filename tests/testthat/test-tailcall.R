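test_that("trimming removes dark-signal G runs and 5' adaptor prefixes", {
  p <- pa_params()
  r <- trim_read(paste0(random_dna(50, alphabet = c("C", "T")),
                        strrep("G", 30)),
                 strrep("F", 80), params = p)
  expect_equal(nchar(r$bases), 50L)
  expect_equal(nchar(r$qual), 50L)

  body <- paste0(strrep("C", 20), strrep("A", 30))
  keep <- trim_read(body, strrep("F", 50), params = p)
  expect_equal(keep$bases, body)

  ad5 <- "TTTAACGCGAATTAATTCTG"
  r2 <- trim_read(paste0("GGGGGG", ad5, body), strrep("F", 76), ad5, p)
  expect_equal(r2$bases, body)
  # one mismatch in a 20-nt adaptor is within the 0.2 error budget
  ad5_mut <- paste0("A", substr(ad5, 2, 20))
  r3 <- trim_read(paste0("GGG", ad5_mut, body), strrep("F", 73), ad5, p)
  expect_equal(r3$bases, body)
})

test_that("preliminary region spans the fuzzy 9-A/6-A anchor windows", {
  p <- pa_params()
  b <- paste0(strrep("C", 25), strrep("A", 30), strrep("CGT", 4))
  pre <- find_preliminary_region(b, p)
  expect_equal(pre$reason, "none")
  # the 1-mismatch windows may each absorb one flanking non-A base
  expect_true(pre$start >= 25L && pre$start <= 26L)
  expect_true(pre$end >= 55L && pre$end <= 56L)
  # refinement then strips the region to exactly the 30 adenosines
  tail <- refine_region(b, pre, p)
  expect_equal(c(tail$start, tail$end), c(26L, 55L))

  expect_equal(find_preliminary_region(strrep("C", 50), p)$reason,
               "no_prelim")
  expect_equal(find_preliminary_region(
    paste0(strrep("C", 25), strrep("A", 8)), p)$reason, "prelim_too_short")
})

test_that("reads whose preliminary region holds fewer than 10 As discard", {
  # the classic sub-minimal case: 9 As between non-A flanks is found by the
  # fuzzy anchors but cannot satisfy the 10-consecutive-A requirement
  b <- paste0(strrep("C", 25), strrep("A", 9), strrep("C", 20))
  call <- call_read(b)
  expect_false(call$discard_reason == "none")
  expect_true(is.na(call$tail_len))
})

test_that("refinement keeps the longest A-bounded segment, ties 5'-most", {
  p <- pa_params()
  whole <- function(b) refine_region(b, list(start = 1L, end = nchar(b)), p)

  b <- strrep("A", 15)
  expect_equal(unlist(whole(b)[c("start", "end")]), c(start = 1L, end = 15L))

  b <- paste0(strrep("A", 12), strrep("C", 5), strrep("A", 30))
  expect_equal(unlist(whole(b)[c("start", "end")]), c(start = 18L, end = 47L))

  b <- paste0(strrep("A", 12), strrep("C", 5), strrep("A", 12))
  expect_equal(unlist(whole(b)[c("start", "end")]), c(start = 1L, end = 12L))

  # interior single mismatches leave no 10-A pure run
  b <- paste0("AAAACAAAA", "CAAAAAAAA")
  expect_equal(whole(b)$reason, "no_pure_run")
})

test_that("quality truncation follows the sliding-window mean rule", {
  p <- pa_params(qc_filter_enabled = TRUE)
  b <- strrep("A", 80)
  q60 <- rep(37L, 60)
  res <- apply_quality_bleed_filter(strrep("A", 60), q60,
                                    list(start = 1L, end = 60L), p)
  expect_false(res$qc_truncated)
  expect_equal(res$end, 60L)

  # 50 high-quality As then 30 low-quality As: the first window with mean
  # below 25 starts at the last Q37 base ((37+10+10)/3 = 19)
  scores <- c(rep(37L, 50), rep(10L, 30))
  res <- apply_quality_bleed_filter(b, scores, list(start = 1L, end = 80L), p)
  expect_true(res$qc_truncated)
  expect_equal(res$end, oracle_qc_end(scores, 1L, 80L))
  expect_equal(res$end, 49L)

  # mean exactly at the threshold does not truncate (strict inequality)
  res <- apply_quality_bleed_filter(strrep("A", 12),
                                    c(rep(37L, 9), rep(25L, 3)),
                                    list(start = 1L, end = 12L), p)
  expect_false(res$qc_truncated)

  # disabled filter is a pass-through
  res <- apply_quality_bleed_filter(b, scores, list(start = 1L, end = 80L),
                                    pa_params())
  expect_equal(res$end, 80L)
})

test_that("quality truncation is monotone and idempotent", {
  p <- pa_params(qc_filter_enabled = TRUE)
  set.seed(404)
  for (i in 1:50) {
    L <- sample(12:60, 1)
    b <- strrep("A", L)
    scores <- sample(c(10L, 20L, 30L, 40L), L, replace = TRUE)
    r1 <- apply_quality_bleed_filter(b, scores, list(start = 1L, end = L), p)
    if (is.na(r1$end)) next
    expect_lte(r1$end, L)
    r2 <- apply_quality_bleed_filter(b, scores,
                                     list(start = r1$start, end = r1$end), p)
    expect_equal(r2$end, r1$end)
    expect_false(r2$qc_truncated && r2$end < r1$end)
  }
})

test_that("adaptor detection applies the floored Hamming budget", {
  p <- pa_params()
  ad <- "CATTGCCTAGAGTCGGACTGA"
  b <- paste0(strrep("C", 20), strrep("A", 40), ad)
  expect_true(detect_adaptor(b, 60L, ad, error_rate = 0.1, params = p))

  mut <- paste0("GGG", substr(ad, 4, 21))  # 3 substitutions in the probe
  b3 <- paste0(strrep("C", 20), strrep("A", 40), mut)
  expect_false(detect_adaptor(b3, 60L, ad, error_rate = 0.1, params = p))
  expect_true(detect_adaptor(b3, 60L, ad, error_rate = 0.2, params = p))

  # tail running to the read end: nothing left to scan
  b_end <- paste0(strrep("C", 20), strrep("A", 40))
  expect_false(detect_adaptor(b_end, 60L, ad, error_rate = 0.35, params = p))
})

test_that("adaptor detection is monotone in the error rate", {
  p <- pa_params()
  ad <- "CATTGCCTAGAGTCGGACTGA"
  set.seed(99)
  for (i in 1:40) {
    downstream <- random_dna(30)
    b <- paste0(strrep("C", 15), strrep("A", 20), downstream)
    rates <- c(0.1, 0.2, 0.25, 0.3, 0.35)
    det <- vapply(rates, function(r)
      detect_adaptor(b, 35L, ad, error_rate = r, params = p), logical(1))
    expect_true(all(diff(det) >= 0))
  }
})

test_that("call_read composes the stages and exposes the anchor", {
  ad <- strrep("CGT", 7)
  b <- paste0(random_dna(25, alphabet = c("C", "G", "T")), strrep("A", 40),
              substr(strrep(ad, 2), 1, 20))
  call <- call_read(b, adaptor3 = ad)
  expect_equal(call$discard_reason, "none")
  expect_equal(call$tail_len, 40L)
  expect_true(call$adaptor_found)
  expect_equal(call$anchor_len, nchar(call$anchor_seq))
  expect_equal(call$anchor_seq, substr(b, 1, call$prelim_start - 1L))

  expect_equal(call_read(strrep("G", 80))$discard_reason, "no_prelim")

  # a short anchor does not block the tail call; mapping flags it later
  short <- call_read(paste0(strrep("C", 15), strrep("A", 40)))
  expect_equal(short$tail_len, 40L)
  expect_lt(short$anchor_len, pa_params()$min_anchor_map_len)
})

test_that("retained calls satisfy the tail invariants", {
  p <- pa_params()
  set.seed(2024)
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:300),
    bases = vapply(1:300, function(i)
      random_dna(sample(40:150, 1), prob = c(0.55, 0.15, 0.15, 0.15)),
      character(1)),
    stringsAsFactors = FALSE)
  reads$qual <- strrep("F", nchar(reads$bases))
  calls <- call_tails(reads, params = p)
  kept <- calls[calls$discard_reason == "none", ]
  expect_gt(nrow(kept), 20)
  for (i in seq_len(nrow(kept))) {
    b <- reads$bases[reads$read_id == kept$read_id[i]]
    expect_gte(kept$tail_start[i], kept$prelim_start[i])
    expect_lte(kept$tail_end[i], kept$prelim_end[i])
    expect_lte(kept$tail_end[i], nchar(b))
    expect_equal(kept$tail_len[i], kept$tail_end[i] - kept$tail_start[i] + 1L)
    seg <- substr(b, kept$tail_start[i], kept$tail_end[i])
    expect_equal(substr(seg, 1, 1), "A")
    expect_equal(substr(seg, nchar(seg), nchar(seg)), "A")
    r <- rle(strsplit(seg, "")[[1]] == "A")
    expect_lt(max(c(0L, r$lengths[!r$values])), p$nonA_split_run)
    expect_gte(max(r$lengths[r$values]), p$min_pure_A_run)
  }
})

test_that("noise-free simulated reads are called at full accuracy", {
  cfg <- sim_config(seed = 31, n_reads = 600, n_genes = 15,
                    substitution_rate = 0, bleed_prob = 0)
  sim <- simulate_reads(cfg)
  calls <- call_tails(sim$reads, adaptor3 = cfg$adaptor3)
  m <- merge(calls, sim$truth, by = "read_id")
  eligible <- m[m$true_tail_len >= 10 & m$anchor_len.y >= 20, ]
  expect_true(all(eligible$discard_reason == "none"))
  visible <- pmin(eligible$true_tail_len,
                  cfg$read_len - eligible$anchor_len.y)
  expect_equal(eligible$tail_len, visible)
})
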