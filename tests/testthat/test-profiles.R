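make_calls <- function(tails, gene = NULL, reason = "none") {
  n <- length(tails)
  out <- data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    prelim_start = 1L, prelim_end = tails + 2L,
    tail_start = 2L, tail_end = tails + 1L, tail_len = tails,
    adaptor_found = FALSE, qc_truncated = FALSE,
    discard_reason = reason, anchor_seq = "", anchor_len = 25L,
    stringsAsFactors = FALSE)
  if (!is.null(gene)) out$gene_id <- gene
  class(out) <- c("pa_calls", "data.frame")
  out
}

test_that("per-gene medians use the lower-median rule", {
  calls <- make_calls(c(40L, 40L, 40L, 10L, 20L, 30L, 100L),
                      gene = c(rep("gA", 3), rep("gB", 4)))
  gm <- gene_medians(calls)
  expect_equal(gm$median_tail_len[gm$gene_id == "gA"], 40L)
  expect_equal(gm$median_tail_len[gm$gene_id == "gB"], 20L)
  expect_equal(gm$n_reads, c(3L, 4L))
  # the pooled sample median ignores gene structure
  expect_equal(attr(gm, "sample_median"), sample_median(calls))
  expect_equal(sample_median(calls), sort(calls$tail_len)[4])
})

test_that("gene medians are invariant to read order and join assignments", {
  set.seed(3)
  tails <- sample(10:120, 40, replace = TRUE)
  genes <- sample(c("g1", "g2", "g3"), 40, replace = TRUE)
  calls <- make_calls(tails, gene = genes)
  perm <- calls[sample(nrow(calls)), ]
  expect_equal(gene_medians(calls), gene_medians(perm),
               ignore_attr = TRUE)
  # assignment path: only unique reads contribute
  calls2 <- make_calls(tails)
  asn <- data.frame(read_id = calls2$read_id,
                    status = ifelse(seq_len(40) <= 30, "unique",
                                    "multimapped"),
                    gene_id = genes, stringsAsFactors = FALSE)
  gm <- gene_medians(calls2, asn)
  expect_equal(sum(gm$n_reads), 30L)
})

test_that("tail histograms bin half-open and normalise", {
  h <- tail_histogram(c(5L, 5L, 15L), bin_width = 10L)
  expect_equal(h$count[h$bin_start == 0], 2L)
  expect_equal(h$count[h$bin_start == 10], 1L)
  expect_equal(sum(h$fraction), 1)
  # exact boundary value falls in the upper bin
  h2 <- tail_histogram(c(10L), bin_width = 10L)
  expect_equal(h2$count[h2$bin_start == 10], 1L)
  # unit width recovers exact counts
  set.seed(4)
  x <- sample(10:50, 100, replace = TRUE)
  h3 <- tail_histogram(x, bin_width = 1L)
  expect_equal(h3$count[match(sort(unique(x)), h3$bin_start)],
               as.integer(table(x)))
  expect_equal(sum(h3$fraction), 1)
})

test_that("per-cycle composition columns are unit-normalised", {
  reads <- data.frame(read_id = c("a", "b"),
                      bases = c("AAAA", "AACC"),
                      qual = c("IIII", "IIII"))
  comp <- base_composition_by_cycle(reads)
  expect_equal(colSums(comp$fraction), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(comp$fraction["A", ]), c(1, 1, 0.5, 0.5))
  # all-A reads give an all-A profile
  onlyA <- data.frame(read_id = "a", bases = strrep("A", 20),
                      qual = strrep("I", 20))
  expect_true(all(base_composition_by_cycle(onlyA)$fraction["A", ] == 1))
})

test_that("junction composition is A upstream and decays with bleeding", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_reads = 800, n_genes = 10,
                    substitution_rate = 0, bleed_prob = 0.6,
                    bleed_len_geom_p = 0.25, tail_mean_range = c(40, 60))
  sim <- simulate_reads(cfg)
  calls <- call_tails(sim$reads, adaptor3 = cfg$adaptor3,
                      params = pa_params(qc_filter_enabled = TRUE))
  jc <- junction_composition(calls, sim$reads)
  up <- jc$fraction["A", as.character(-(10:1))]
  expect_true(all(up == 1))
  post <- jc$fraction["A", as.character(0:14)]
  # bled adenosines elevate the A fraction right after the called tail,
  # and the elevation decays into the adaptor
  expect_gt(post[1], 0.3)
  expect_lt(mean(post[11:15]), mean(post[1:3]))
  covered <- jc$coverage > 0
  expect_equal(unname(colSums(jc$fraction)[covered]),
               rep(1, sum(covered)), tolerance = 1e-9)
})

test_that("the cumulative fraction is a right-continuous ECDF", {
  cf <- cumulative_fraction(c(40L, 40L, 40L))
  expect_equal(cf$tail_len, 40L)
  expect_equal(cf$cum_fraction, 1)
  set.seed(5)
  x <- sample(10:200, 500, replace = TRUE)
  cf2 <- cumulative_fraction(x)
  expect_true(all(diff(cf2$cum_fraction) > 0))
  expect_equal(cf2$cum_fraction[nrow(cf2)], 1)
  # the length at which the curve crosses 0.5 is the lower median
  med <- cf2$tail_len[which(cf2$cum_fraction >= 0.5)[1]]
  expect_lte(abs(med - sort(x)[floor((length(x) + 1) / 2)]), 1)
})

test_that("the adaptor sweep is monotone and mode-consistent", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  # half the reads carry an exact adaptor, half carry 3 substitutions
  # (positions 8-10, away from the junction and introducing no adenosine)
  mut <- paste0(substr(ad, 1, 7), "GGG", substr(ad, 11, 21))
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:40),
    bases = c(replicate(20, paste0(strrep("C", 25), strrep("A", 40), ad)),
              replicate(20, paste0(strrep("C", 25), strrep("A", 40), mut))),
    stringsAsFactors = FALSE)
  reads$qual <- strrep("F", nchar(reads$bases))
  calls <- call_tails(reads, adaptor3 = ad)
  sw <- adaptor_detection_sweep(calls, reads, ad)
  expect_true(all(diff(sw$fraction) >= 0))
  expect_equal(sw$fraction[sw$error_rate == 0.1], 0.5)
  expect_equal(sw$fraction[sw$error_rate == 0.2], 1)

  # tails reaching the read end count against the default denominator only
  reads2 <- rbind(reads,
                  data.frame(read_id = "rend",
                             bases = paste0(strrep("C", 25), strrep("A", 60)),
                             qual = strrep("F", 85)))
  calls2 <- call_tails(reads2, adaptor3 = ad)
  sw_all <- adaptor_detection_sweep(calls2, reads2, ad)
  sw_elig <- adaptor_detection_sweep(calls2, reads2, ad,
                                     eligible_only = TRUE)
  expect_equal(sw_all$n[1], 41L)
  expect_equal(sw_elig$n[1], 40L)
  expect_equal(sw_elig$fraction[sw_elig$error_rate == 0.2], 1)
  expect_lt(sw_all$fraction[sw_all$error_rate == 0.2], 1)
})

test_that("median concordance joins genes and reports both correlations", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  n_reads = 10L, median_tail_len = c(50L, 70L, 90L, 110L))
  b <- a
  cc <- median_concordance(a, b)
  expect_equal(cc$pearson, 1)
  expect_equal(cc$spearman, 1)
  b$median_tail_len <- a$median_tail_len + 10L
  cc2 <- median_concordance(a, b)
  expect_equal(cc2$pearson, 1)
  expect_equal(cc2$mean_difference, 10)
  # independent medians decorrelate
  set.seed(6)
  big_a <- data.frame(gene_id = sprintf("g%04d", 1:1000), n_reads = 5L,
                      median_tail_len = sample(20:150, 1000, replace = TRUE))
  big_b <- big_a
  big_b$median_tail_len <- sample(20:150, 1000, replace = TRUE)
  expect_lt(abs(median_concordance(big_a, big_b)$pearson), 0.1)
  expect_error(median_concordance(a[1:2, ], b[1:2, ]), "3 shared genes")
})
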