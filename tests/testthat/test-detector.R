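test_that("quality_trim applies the 3'-trim-then-length-filter rule", {
  q <- function(scores) intToUtf8(scores + 33)
  # 40-base read, last 10 scores 20: trimmed to 30 < 32 -> discarded
  r1 <- read_df(rand_seq(40), q(c(rep(38, 30), rep(20, 10))))
  expect_equal(nrow(quality_trim(r1)), 0L)
  # nothing below threshold -> unchanged
  r2 <- read_df(rand_seq(40), q(rep(36, 40)))
  expect_equal(quality_trim(r2)$seq, r2$seq)
  # 35-base read, last 3 scores 2 -> trimmed to 32, kept (boundary)
  r3 <- read_df(rand_seq(35), q(c(rep(40, 32), rep(2, 3))))
  t3 <- quality_trim(r3)
  expect_equal(nchar(t3$seq), 32L)
  expect_equal(nchar(t3$qual), 32L)
  # trimming stops at the first 3' base reaching the threshold, even if
  # low-quality bases remain further inside
  r4 <- read_df(rand_seq(40), q(c(rep(40, 20), rep(10, 15), 35, rep(10, 4))))
  expect_equal(nchar(quality_trim(r4)$seq), 36L)
  # mismatched quality length is a format error
  r5 <- data.frame(id = "x", seq = "ACGT", qual = "III")
  expect_error(quality_trim(r5), class = "kmerpanel_format_error")
})

test_that("count_panel counts overlapping canonical matches on both strands", {
  p <- build_genus_panel(list("GTACGTAC"), k = 4)
  p$kmers <- "GTAC"  # pin the panel to the documented example
  expect_equal(count_panel(p, "GGTACC")$count, 1L)
  expect_equal(count_panel(p, "GTACGTAC")$count, 2L)
  expect_equal(count_panel(p, character())$count, 0L)
  expect_equal(count_panel(p, character())$reads_scanned, 0L)
  # reads shorter than k warn and count zero
  expect_warning(tab <- count_panel(p, c("AC", "GT")))
  expect_equal(sum(tab$count), 0L)
})

test_that("count_panel is strand-invariant and matches the naive scanner", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    g <- rand_seq(300)
    panel <- build_genus_panel(list(g), k = k)
    if (length(panel$kmers) > 50)
      panel$kmers <- sort(sample(panel$kmers, 50))
    reads <- replicate(60, substr(g, (s <- sample(1:250, 1)), s + 39))
    tab <- count_panel(panel, reads)
    expect_equal(tab$count, o_count(panel$kmers, reads, k))
    # reverse-complementing every read leaves counts unchanged
    rc_reads <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads)))
    expect_equal(count_panel(panel, rc_reads)$count, tab$count)
  }
})

test_that("detected_count applies the frequency cutoff inclusively", {
  p <- build_genus_panel(list("GTACGTAC"), k = 4)
  p$kmers <- "GTAC"
  tab <- count_panel(p, "GGTACC")  # GTAC:1
  expect_equal(detected_count(tab, 1), 1L)
  expect_equal(detected_count(tab, 2), 0L)
  tab0 <- count_panel(p, character())
  expect_equal(detected_count(tab0, 1), 0L)
  expect_error(detected_count(tab, 0), class = "kmerpanel_param_error")
  # monotone non-increasing in min_freq
  set.seed(32)
  g <- rand_seq(400)
  pan <- build_genus_panel(list(g), k = 5)
  reads <- replicate(100, substr(g, (s <- sample(1:350, 1)), s + 29))
  tab2 <- count_panel(pan, reads)
  det <- vapply(1:5, function(m) detected_count(tab2, m), 0L)
  expect_false(is.unsorted(rev(det)))
})

test_that("subsample_reads is deterministic, nested, and validates n", {
  reads <- read_df(replicate(50, rand_seq(20)))
  full <- subsample_reads(reads, 50, seed = 3)
  expect_setequal(full$id, reads$id)
  expect_equal(sort(full$seq), sort(reads$seq))
  expect_equal(nrow(subsample_reads(reads, 0, seed = 3)), 0L)
  s1 <- subsample_reads(reads, 10, seed = 3)
  s2 <- subsample_reads(reads, 10, seed = 3)
  expect_identical(s1, s2)
  # nesting: size-10 subset contained in size-30 subset under same seed
  s3 <- subsample_reads(reads, 30, seed = 3)
  expect_true(all(s1$id %in% s3$id))
  expect_error(subsample_reads(reads, 51, seed = 3),
               class = "kmerpanel_param_error")
  expect_match(tryCatch(subsample_reads(reads, 51), error = conditionMessage),
               "51.*50")
})

test_that("sensitivity_curve is nested-monotone and ends at the full count", {
  set.seed(33)
  g <- rand_seq(2000)
  panel <- build_genus_panel(list(g), k = 8)
  reads <- simulate_reads(c(g = g), 400, 50, error_rate = 0, seed = 5)
  curve <- sensitivity_curve(panel, reads, c(50, 100, 200, 400),
                             min_freq = 1, seed = 9)
  expect_false(is.unsorted(curve$detected))
  full <- detected_count(count_panel(panel, reads$seq), 1)
  expect_equal(curve$detected[4], full)
  expect_equal(curve$fraction_detected, curve$detected / length(panel$kmers))
  expect_error(sensitivity_curve(panel, reads, c(100, 500)),
               class = "kmerpanel_param_error")
  expect_error(sensitivity_curve(panel, reads, c(200, 100)),
               class = "kmerpanel_param_error")
})

test_that("call_presence uses inclusive thresholds and the default table", {
  expect_true(call_presence(1500, 31179, "Lupinus")$present)
  expect_false(call_presence(1499, 31179, "Lupinus")$present)
  expect_false(call_presence(0, 31179, "Lupinus")$present)
  # built-in defaults resolve per taxon
  expect_equal(call_presence(1, 10, "Lupinus albus",
                             threshold = 5)$threshold, 5L)
  defs <- default_thresholds()
  expect_equal(unname(defs[c("Lupinus", "Lupinus albus", "Lupinus luteus",
                             "Lupinus westianus")]),
               c(1500L, 7500L, 4000L, 4300L))
  expect_error(call_presence(10, 100, "unknown taxon"),
               class = "kmerpanel_param_error")
  expect_error(call_presence(200, 100, "Lupinus"),
               class = "kmerpanel_param_error")
})

test_that("screen_fasta reports detected panel k-mers in an assembly", {
  set.seed(34)
  g <- rand_seq(600)
  panel <- build_genus_panel(list(g), k = 6)
  # a panel screened against its own source genome is fully contained
  expect_equal(screen_fasta(panel, g)$fraction, 1.0)
  # a genome subtracted during construction contains nothing
  nt <- rand_seq(600)
  p2 <- build_genus_panel(list(g), list(nt), k = 6)
  expect_equal(screen_fasta(p2, nt)$detected, 0L)
  # naive-scan example
  p3 <- p2; p3$kmers <- "GTACGT"
  r <- screen_fasta(p3, "TTGTACGTTT")
  expect_equal(r$detected, 1L)
  expect_equal(r$fraction, 1.0)
  expect_error(screen_fasta(panel, character()),
               class = "kmerpanel_param_error")
})
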