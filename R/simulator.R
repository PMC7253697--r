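# Synthetic data: target clades, divergent non-target genomes, and
# error-bearing short-read mixtures. Everything is deterministic for a
# given seed, so pipeline outputs are byte-reproducible.

#' Simulation configuration
#'
#' Desk-scale defaults emulate the structure of the real setting at a
#' size that runs in seconds: a small clade of closely related target
#' "plastid" genomes, a set of clearly divergent non-target genomes,
#' and short single-end reads with substitution errors, mixed at a
#' controllable target fraction (an in-silico analogue of spiking a
#' known percentage of target flour into a food sample).
#'
#' @param genome_length genome length in bases (default 20000, roughly
#'   an order of magnitude below a real plastid genome).
#' @param n_target_species number of target clade genomes (default 3).
#' @param within_clade_divergence substitutions/site between target
#'   genomes and their common ancestor (default 0.005, congeneric-level
#'   plastid divergence).
#' @param n_nontarget_species number of non-target genomes (default 7).
#' @param nontarget_divergence substitutions/site for non-targets
#'   (default 0.05, family-level divergence).
#' @param read_length read length in bases (default 85, single-end
#'   short-read scale).
#' @param error_rate per-base substitution error rate (default 0.001,
#'   typical modern Illumina substitution error).
#' @param n_reads number of reads to simulate (default 1e5).
#' @param target_fraction proportion of reads drawn from the target
#'   genome in a mixture (default 0.05).
#' @param quality_score constant Phred score written for simulated
#'   bases (default 38).
#' @param seed master RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000, n_target_species = 3,
                       within_clade_divergence = 0.005,
                       n_nontarget_species = 7, nontarget_divergence = 0.05,
                       read_length = 85, error_rate = 0.001, n_reads = 1e5,
                       target_fraction = 0.05, quality_score = 38, seed = 1) {
  cfg <- list(genome_length = genome_length,
              n_target_species = n_target_species,
              within_clade_divergence = within_clade_divergence,
              n_nontarget_species = n_nontarget_species,
              nontarget_divergence = nontarget_divergence,
              read_length = read_length, error_rate = error_rate,
              n_reads = n_reads, target_fraction = target_fraction,
              quality_score = quality_score, seed = seed)
  rates <- c(cfg$within_clade_divergence, cfg$nontarget_divergence,
             cfg$error_rate, cfg$target_fraction)
  if (any(rates < 0 | rates > 1))
    stop_param("divergences, error_rate and target_fraction must lie in [0,1]")
  if (cfg$genome_length < 1) stop_param("genome_length must be >= 1")
  if (cfg$read_length > cfg$genome_length)
    stop_param("read_length (%d) exceeds genome_length (%d)",
               cfg$read_length, cfg$genome_length)
  if (cfg$n_reads < 0) stop_param("n_reads must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Random genome sequence
#'
#' I.i.d. uniform A/C/G/T sequence, deterministic per seed. Optionally a
#' reverse-complemented copy of the terminal segment is appended, a
#' coarse mimic of the inverted repeat of plastid genomes (which
#' duplicates k-mers within one genome but, being a reverse complement,
#' adds no new canonical k-mers from the repeated stretch).
#'
#' @param length genome length in bases (>= 1).
#' @param seed RNG seed.
#' @param inverted_repeat length of the terminal segment to duplicate in
#'   reverse complement (default 0 = none).
#' @return A single character string.
#' @export
random_genome <- function(length, seed = 1, inverted_repeat = 0) {
  if (!is.numeric(length) || length < 1)
    stop_param("genome length must be >= 1")
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  if (inverted_repeat > 0) {
    ir <- substr(seq, nchar(seq) - inverted_repeat + 1L, nchar(seq))
    seq <- paste0(seq, rc_string(ir))
  }
  seq
}

# reverse complement for arbitrary-length strings (reads/genomes; the
# 2-bit kernel only covers k <= 32)
rc_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Mutate a sequence at a fixed substitution rate
#'
#' Each site is independently substituted with probability `rate`; a
#' substituted base is drawn uniformly from the three other bases, so a
#' rate of 1 changes every position. Length is preserved (no indels:
#' the downstream method is exact k-mer matching, for which
#' substitutions are the operative error mode).
#'
#' @param seq single character string over A/C/G/T.
#' @param rate substitution probability per site, in \[0,1\].
#' @param seed RNG seed.
#' @return The mutated sequence (character string).
#' @export
mutate_genome <- function(seq, rate, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop_param("rate must lie in [0,1]")
  if (rate == 0 || nchar(seq) == 0L) return(seq)
  with_seed(seed, {
    bases <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(bases)) < rate)
    if (length(hit)) {
      alt <- c("A", "C", "G", "T")
      # uniform choice among the three non-identical bases
      repl <- vapply(bases[hit],
                     function(b) sample(setdiff(alt, b), 1L), "")
      bases[hit] <- repl
    }
    paste(bases, collapse = "")
  })
}

#' Simulate a target clade and non-target genomes
#'
#' One random ancestor genome; target genomes are independent mutants
#' at `within_clade_divergence`, non-targets at `nontarget_divergence`.
#' All derived seeds are functions of `config$seed`, so the clade is
#' fully deterministic.
#'
#' @param config a [sim_config()].
#' @return List with `ancestor` (string), `targets` and `nontargets`
#'   (named character vectors).
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  anc <- random_genome(config$genome_length, seed = config$seed)
  # derived seeds folded into 32-bit range so any master seed is safe
  sbase <- (as.numeric(config$seed) %% 2e6) * 1000
  tseeds <- as.integer(sbase + seq_len(config$n_target_species))
  targets <- setNames(
    vapply(tseeds, function(s)
      mutate_genome(anc, config$within_clade_divergence, seed = s), ""),
    sprintf("target_%d", seq_len(config$n_target_species)))
  nseeds <- as.integer(sbase + 500 + seq_len(config$n_nontarget_species))
  nontargets <- setNames(
    vapply(nseeds, function(s)
      mutate_genome(anc, config$nontarget_divergence, seed = s), ""),
    sprintf("nontarget_%d", seq_len(config$n_nontarget_species)))
  list(ancestor = anc, targets = targets, nontargets = nontargets)
}

#' Simulate single-end reads from weighted genomes
#'
#' Each read picks a source genome by weight, a uniform start position,
#' and a uniform strand (the window or its reverse complement), then
#' receives independent per-base substitution errors. Qualities are a
#' constant score (trimming behaviour is exercised separately with
#' crafted quality strings).
#'
#' @param genomes named character vector of genome sequences.
#' @param n_reads number of reads.
#' @param read_length read length (must not exceed any genome length).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @param weights sampling weights per genome (default uniform).
#' @param quality_score constant Phred score (default 38).
#' @param circular treat genomes as circular (reads may wrap around the
#'   origin, as on a real plastid chromosome), giving uniform window
#'   coverage with no linear edge effect. Default FALSE.
#' @return data.frame with columns `id`, `seq`, `qual` plus truth
#'   columns `source_genome`, `strand`, `start`, `n_errors`.
#' @export
simulate_reads <- function(genomes, n_reads, read_length, error_rate = 0,
                           seed = 1, weights = NULL, quality_score = 38,
                           circular = FALSE) {
  genomes <- unlist(genomes)
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("genome_%d", seq_along(genomes))
  glen <- nchar(genomes)
  if (any(read_length > glen))
    stop_param("read_length (%d) exceeds a genome length (%d)",
               read_length, min(glen))
  if (n_reads == 0)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), source_genome = character(),
                      strand = character(), start = integer(),
                      n_errors = integer(), stringsAsFactors = FALSE))
  if (is.null(weights)) weights <- rep(1, length(genomes))
  with_seed(seed, {
    src <- sample.int(length(genomes), n_reads, replace = TRUE,
                      prob = weights)
    if (circular) {
      start <- floor(runif(n_reads, 1, glen[src] + 1))
      doubled <- paste0(genomes, substr(genomes, 1L, read_length))
      seqs <- substring(doubled[src], start, start + read_length - 1L)
    } else {
      start <- floor(runif(n_reads, 1, glen[src] - read_length + 2))
      seqs <- substring(genomes[src], start, start + read_length - 1L)
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    rev <- strand == "-"
    if (any(rev)) seqs[rev] <- rc_string(seqs[rev])
    n_err <- integer(n_reads)
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      hit <- which(n_err > 0L)
      alt <- c("A", "C", "G", "T")
      for (i in hit) {
        b <- strsplit(seqs[i], "")[[1]]
        pos <- sample.int(read_length, n_err[i])
        for (p in pos) b[p] <- sample(setdiff(alt, b[p]), 1L)
        seqs[i] <- paste(b, collapse = "")
      }
    }
    data.frame(id = sprintf("read_%d", seq_len(n_reads)), seq = seqs,
               qual = strrep(intToUtf8(quality_score + 33L), read_length),
               source_genome = names(genomes)[src], strand = strand,
               start = as.integer(start), n_errors = n_err,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a target/background read mixture
#'
#' The in-silico analogue of spiking a known mass fraction of target
#' material into a background sample: each read comes from the
#' designated target genome with probability `config$target_fraction`
#' and from a background (non-target) genome otherwise.
#'
#' @param config a [sim_config()].
#' @param clade a clade from [simulate_clade()] (the same one any panel
#'   under test was built from).
#' @param target index or name of the target genome in `clade$targets`
#'   (default 1).
#' @param background index or name of the background genome in
#'   `clade$nontargets` (default 1).
#' @return List with `reads` (read data.frame incl. truth columns),
#'   `truth` (the truth columns only) and `n_target_reads`.
#' @export
simulate_mixture <- function(config, clade, target = 1, background = 1) {
  stopifnot(inherits(config, "sim_config"))
  genomes <- c(clade$targets[target], clade$nontargets[background])
  reads <- simulate_reads(genomes, config$n_reads, config$read_length,
                          error_rate = config$error_rate,
                          seed = as.integer((as.numeric(config$seed) + 7) %%
                                              2147483647),
                          weights = c(config$target_fraction,
                                      1 - config$target_fraction),
                          quality_score = config$quality_score)
  truth <- reads[, c("id", "source_genome", "strand", "start", "n_errors")]
  list(reads = reads, truth = truth,
       n_target_reads = sum(reads$source_genome == names(genomes)[1L]))
}
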