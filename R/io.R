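# File formats: FASTA/FASTQ input (Biostrings-backed, gzip transparent),
# plain-text panel files, report/curve TSVs.

open_text <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a FASTA file
#'
#' Plain or gzipped, wrapped lines and multi-record files allowed. The
#' record id is the header up to the first whitespace; the remainder is
#' kept as the description.
#'
#' @param source path to a FASTA file.
#' @return data.frame with columns `id`, `desc`, `seq`; attribute
#'   `source` records the path. Duplicate ids raise a warning but both
#'   records are kept; an empty file yields zero rows with a warning.
#' @export
read_fasta <- function(source) {
  if (!file.exists(source)) stop_io("cannot read FASTA file: %s", source)
  first <- first_nonblank_char(source)
  if (is.na(first)) {
    warning(sprintf("empty FASTA file: %s", source))
    out <- data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE)
    attr(out, "source") <- source
    return(out)
  }
  if (first != ">")
    stop_format("not a FASTA file (first character '%s', expected '>'): %s",
                first, source)
  x <- tryCatch(Biostrings::readBStringSet(source, format = "fasta"),
                error = function(e)
                  stop_format("malformed FASTA %s: %s", source,
                              conditionMessage(e)))
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id))
    warning(sprintf("duplicate FASTA ids in %s: %s", source,
                    paste(unique(id[duplicated(id)]), collapse = ", ")))
  out <- data.frame(id = id, desc = desc, seq = toupper(as.character(x)),
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  out
}

first_nonblank_char <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    line <- trimws(line)
    if (nzchar(line)) return(substr(line, 1L, 1L))
  }
}

#' Read a FASTQ file
#'
#' Strict four-line records, Phred+33 qualities, plain or gzipped.
#' Phred+64 input is not supported and not auto-detected; quality
#' characters outside the Phred+33 printable range are rejected when
#' scores are used. Parsed directly rather than through a permissive
#' reader so that a truncated record, a missing '+' line or a
#' sequence/quality length mismatch is reported with its record
#' ordinal instead of being silently padded.
#'
#' @param source path to a FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(source) {
  if (!file.exists(source)) stop_io("cannot read FASTQ file: %s", source)
  con <- open_text(source)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop_format("truncated FASTQ %s: record %d is incomplete",
                source, length(lines) %/% 4L + 1L)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop_format("malformed FASTQ %s: record %d does not start with '@'",
                source, bad[1L])
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop_format("malformed FASTQ %s: record %d lacks its '+' line",
                source, bad[1L])
  bad <- which(nchar(ql) != nchar(sq))
  if (length(bad))
    stop_format("malformed FASTQ %s: record %d quality length (%d) != sequence length (%d)",
                source, bad[1L], nchar(ql[bad[1L]]), nchar(sq[bad[1L]]))
  data.frame(id = sub("\\s.*$", "", substring(hd, 2L)),
             seq = sq, qual = ql, stringsAsFactors = FALSE)
}

#' Write FASTA / FASTQ
#'
#' @param records data.frame with `id`, `seq` (and `qual` for FASTQ).
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @param width line-wrap width for FASTA (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records))
    records <- data.frame(id = names(records) %||%
                            sprintf("seq_%d", seq_along(records)),
                          seq = records, stringsAsFactors = FALSE)
  con <- open_text(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  con <- open_text(path, "wt")
  on.exit(close(con))
  if (nrow(records))
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n",
                      records$qual), con)
  invisible(path)
}

#' Write / read a panel file
#'
#' Panels persist as plain text (gzip accepted) for auditability:
#' header lines beginning `#` carry k, taxon, rank and one provenance
#' entry per line; the body is one uppercase canonical k-mer per line,
#' lexicographically sorted, no duplicates.
#'
#' @param panel a `kmer_panel`.
#' @param path file path (`.gz` for compression).
#' @return `write_panel`: `path` invisibly; `read_panel`: the
#'   reconstructed `kmer_panel` (lossless round-trip including
#'   provenance).
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  con <- open_text(path, "wt")
  on.exit(close(con))
  writeLines(c("# kmerpanel panel v1",
               paste0("# k: ", panel$k),
               paste0("# taxon: ", panel$taxon),
               paste0("# rank: ", panel$rank),
               paste0("# provenance: ", panel$provenance)), con)
  if (length(panel$kmers)) writeLines(panel$kmers, con)
  invisible(path)
}

#' @rdname write_panel
#' @param source panel file path.
#' @param strict if TRUE (default) an unsorted or duplicated body is a
#'   format error; if FALSE the body is re-sorted and deduplicated.
#' @export
read_panel <- function(source, strict = TRUE) {
  if (!file.exists(source)) stop_io("cannot read panel file: %s", source)
  con <- open_text(source)
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- grepl("^#", lines)
  head_lines <- lines[hdr]
  body <- lines[!hdr & nzchar(lines)]
  get_field <- function(name) {
    m <- grep(sprintf("^# %s: ", name), head_lines, value = TRUE)
    sub(sprintf("^# %s: ", name), "", m)
  }
  k <- suppressWarnings(as.integer(get_field("k")[1L]))
  if (is.na(k)) stop_format("panel file %s lacks a '# k:' header", source)
  bad <- which(nchar(body) != k | !grepl("^[ACGT]+$", body))
  if (length(bad))
    stop_format("panel file %s: invalid k-mer at body line %d ('%s')",
                source, bad[1L], body[bad[1L]])
  if (is.unsorted(body, strictly = TRUE)) {
    if (strict)
      stop_format("panel file %s: body not strictly sorted (use strict=FALSE to re-sort)",
                  source)
    body <- sort(unique(body))
  }
  new_kmer_panel(body, k,
                 taxon = get_field("taxon")[1L] %||% "unknown",
                 rank = get_field("rank")[1L] %||% "genus",
                 provenance = get_field("provenance"))
}

#' Write a detection report / sensitivity curve TSV
#'
#' Fixed column sets: report `taxon, panel_size, reads_scanned,
#' min_freq, detected, fraction_detected, threshold, present`; curve
#' `n_reads, detected, fraction_detected`.
#'
#' @param result a list as returned by [detect_taxon()] together with
#'   `min_freq`, or a `sensitivity_curve`.
#' @param path output TSV path.
#' @param min_freq detection cutoff used (recorded in the report).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, min_freq = 1) {
  call <- result$call
  tab <- result$table
  df <- data.frame(taxon = call$taxon, panel_size = call$panel_size,
                   reads_scanned = tab$reads_scanned,
                   min_freq = as.integer(min_freq),
                   detected = call$detected,
                   fraction_detected = call$detected / call$panel_size,
                   threshold = call$threshold, present = call$present,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @param curve a `sensitivity_curve`.
#' @export
write_curve <- function(curve, path) {
  write.table(as.data.frame(curve)[, c("n_reads", "detected",
                                       "fraction_detected")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Central defaults mirrored by the command-line interface: k = 32,
#' detection cutoff 1, panel-filter removal cutoff 1, the built-in
#' presence threshold table, the standard subsample size grid (1e3,
#' 1e4, 1e5, 2.5e5, 5e5, 1e6, 1e7, 1e8), trimming at quality 35 /
#' minimum length 32, seed 1.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(k = 32L, min_freq = 1L, removal_min_freq = 1L,
              thresholds = default_thresholds(),
              sizes = c(1e3, 1e4, 1e5, 2.5e5, 5e5, 1e6, 1e7, 1e8),
              seed = 1L, trim_quality = 35L, trim_min_length = 32L,
              verbosity = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_param("unknown run_config field(s): %s",
                              paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}
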