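test_that("read_fasta handles wrapping, descriptions, gzip and edge cases", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">a some description", "AC", "GT", ">b", "TTTT"), p)
  fa <- read_fasta(p)
  expect_equal(fa$id, c("a", "b"))
  expect_equal(fa$desc[1], "some description")
  expect_equal(fa$seq, c("ACGT", "TTTT"))
  # gzip and plain encodings yield identical records
  pgz <- tmp_fasta(c("ACGTACGT", "GGCC"), c("x", "y"), gz = TRUE)
  ppl <- tmp_fasta(c("ACGTACGT", "GGCC"), c("x", "y"))
  expect_equal(read_fasta(pgz)[c("id", "seq")], read_fasta(ppl)[c("id", "seq")])
  # empty file: zero records plus a warning
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_warning(fe <- read_fasta(empty))
  expect_equal(nrow(fe), 0L)
  # not FASTA
  bad <- tempfile(); writeLines("ACGT", bad)
  expect_error(read_fasta(bad), class = "kmerpanel_format_error")
  # duplicate ids: warning, both kept
  dup <- tmp_fasta(c("AAAA", "CCCC"), c("d", "d"))
  expect_warning(fd <- read_fasta(dup))
  expect_equal(nrow(fd), 2L)
  expect_error(read_fasta("no_such_file.fa"), class = "kmerpanel_io_error")
})

test_that("read_fastq parses records and rejects malformed input", {
  p <- tmp_fastq(c("ACGTACGT", "TTTTAAAA"))
  fq <- read_fastq(p)
  expect_equal(fq$seq, c("ACGTACGT", "TTTTAAAA"))
  expect_equal(nchar(fq$qual), c(8L, 8L))
  # gzip and plain encodings identical
  pgz <- tmp_fastq(c("ACGTACGT", "TTTTAAAA"), gz = TRUE)
  expect_equal(read_fastq(pgz), fq)
  # quality shorter than sequence
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "III"), bad)
  expect_error(read_fastq(bad), class = "kmerpanel_format_error")
  # truncated record
  trunc <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  expect_error(read_fastq(trunc), class = "kmerpanel_format_error")
})

test_that("panel files round-trip losslessly and validate on read", {
  set.seed(71)
  panel <- build_genus_panel(list(rand_seq(300), rand_seq(300)), k = 6,
                             taxon = "roundtrip")
  panel <- filter_panel_with_reads(panel, list(rand_seq(50)))
  path <- tempfile(fileext = ".panel")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back, panel)
  # gzip round-trip
  pgz <- tempfile(fileext = ".panel.gz")
  write_panel(panel, pgz)
  expect_equal(read_panel(pgz)$kmers, panel$kmers)
  # empty panel: headers only
  ep <- build_genus_panel(list("AAAAAA", "CCCCCC"), k = 4)
  epath <- tempfile(); write_panel(ep, epath)
  expect_length(read_panel(epath)$kmers, 0)
  # unsorted body: strict error, lenient re-sort
  upath <- tempfile()
  writeLines(c("# kmerpanel panel v1", "# k: 4", "# taxon: t", "# rank: genus",
               "CCCC", "AAAA"), upath)
  expect_error(read_panel(upath), class = "kmerpanel_format_error")
  expect_equal(read_panel(upath, strict = FALSE)$kmers, c("AAAA", "CCCC"))
  # invalid body line
  bpath <- tempfile()
  writeLines(c("# k: 4", "ACGT", "ACGU"), bpath)
  expect_error(read_panel(bpath), class = "kmerpanel_format_error")
})

test_that("report and curve TSVs have the fixed column contract", {
  set.seed(72)
  g <- rand_seq(1500)
  panel <- build_genus_panel(list(g), k = 8, taxon = "tsv")
  reads <- simulate_reads(c(g = g), 300, 50, seed = 3)
  res <- detect_taxon(panel, reads, min_freq = 1, threshold = 10,
                      trim = FALSE)
  rpath <- tempfile(fileext = ".tsv")
  write_report(res, rpath, min_freq = 1)
  rep <- read.table(rpath, header = TRUE, sep = "\t")
  expect_equal(names(rep),
               c("taxon", "panel_size", "reads_scanned", "min_freq",
                 "detected", "fraction_detected", "threshold", "present"))
  expect_equal(rep$detected, detected_count(res$table, 1))
  cpath <- tempfile(fileext = ".tsv")
  curve <- sensitivity_curve(panel, reads, c(100, 300), seed = 4)
  write_curve(curve, cpath)
  cv <- read.table(cpath, header = TRUE, sep = "\t")
  expect_equal(names(cv), c("n_reads", "detected", "fraction_detected"))
  expect_equal(nrow(cv), 2L)
})

test_that("run_config carries the documented defaults", {
  cfg <- run_config()
  expect_equal(cfg$k, 32L)
  expect_equal(cfg$sizes, c(1e3, 1e4, 1e5, 2.5e5, 5e5, 1e6, 1e7, 1e8))
  expect_equal(cfg$trim_quality, 35L)
  expect_equal(cfg$trim_min_length, 32L)
  expect_equal(cfg$removal_min_freq, 1L)
  expect_equal(run_config(min_freq = 2L)$min_freq, 2L)
  expect_error(run_config(bogus = 1), class = "kmerpanel_param_error")
})

test_that("cli: usage and error exit codes", {
  expect_equal(suppressMessages(run_cli(character())), 1L)
  expect_equal(suppressMessages(run_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(run_cli(c("build-genus", "--taxon", "t",
                                          "--out", tempfile()))), 1L)
  # data errors exit 2
  expect_equal(suppressMessages(
    run_cli(c("detect", "--panel", "missing.panel", "--reads", "x.fastq",
              "--out", tempfile()))), 2L)
})

test_that("cli: end-to-end simulate -> build -> detect round trip", {
  dir <- tempfile(); dir.create(dir)
  expect_equal(suppressMessages(run_cli(c(
    "simulate", "--out-dir", dir, "--genome-length", "3000",
    "--n-reads", "4000", "--read-length", "60", "--error-rate", "0",
    "--target-fraction", "0.5", "--seed", "5", "--quiet"))), 0L)
  expect_true(file.exists(file.path(dir, "mixture.fastq")))
  panel_path <- file.path(dir, "panel.txt")
  expect_equal(suppressMessages(run_cli(c(
    "build-genus", "--target", file.path(dir, "targets.fasta"),
    "--nontarget", file.path(dir, "nontargets.fasta"),
    "--k", "16", "--taxon", "sim-target", "--out", panel_path,
    "--quiet"))), 0L)
  panel <- read_panel(panel_path)
  expect_gt(length(panel$kmers), 0)
  report <- file.path(dir, "report.tsv")
  expect_equal(suppressMessages(run_cli(c(
    "detect", "--panel", panel_path, "--reads",
    file.path(dir, "mixture.fastq"), "--threshold", "10",
    "--no-trim", "--out", report, "--quiet"))), 0L)
  rep <- read.table(report, header = TRUE, sep = "\t")
  # library()-level check of the same computation
  reads <- read_fastq(file.path(dir, "mixture.fastq"))
  expect_equal(rep$detected,
               detected_count(count_panel(panel, reads$seq), 1))
  expect_true(rep$present)
  # curve with sizes exceeding the read count exits 1, naming both numbers
  msgs <- capture.output(
    code <- run_cli(c("curve", "--panel", panel_path, "--reads",
                      file.path(dir, "mixture.fastq"), "--sizes",
                      "1000,999999", "--no-trim", "--out", tempfile(),
                      "--quiet")), type = "message")
  expect_equal(code, 1L)
  expect_match(paste(msgs, collapse = " "), "999999")
})
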