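# Panel construction: set algebra on canonical k-mer sets.
#
# A "genome" argument is one of: a FASTA file path (possibly gzipped), a
# character vector of sequences, or a data.frame with a `seq` column (as
# returned by read_fasta). One genome = one unit for intersection
# purposes, even if it holds several records (multi-contig assemblies):
# records within a genome are unioned.

as_genome_seqs <- function(x, what = "genome") {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (is.data.frame(x)) {
    if (!"seq" %in% names(x)) stop_param("%s data.frame needs a 'seq' column", what)
    return(list(seqs = as.character(x$seq), label = attr(x, "source") %||% "<in-memory>"))
  }
  if (!is.character(x)) stop_param("%s must be a file path or character sequences", what)
  if (length(x) == 1L && !grepl("^[ACGTNacgtn]*$", x)) {
    if (!file.exists(x)) stop_io("cannot read %s file: %s", what, x)
    fa <- read_fasta(x)
    return(list(seqs = as.character(fa$seq), label = x))
  }
  list(seqs = x, label = sprintf("<in-memory:%d seq%s>", length(x),
                                 if (length(x) == 1L) "" else "s"))
}

as_genome_list <- function(x, what = "genome") {
  if (is.null(x) || (is.list(x) && length(x) == 0L) ||
      (is.character(x) && length(x) == 0L)) return(list())
  if (is.data.frame(x) || inherits(x, "DNAStringSet") ||
      (is.character(x) && length(x) == 1L)) x <- list(x)
  if (is.character(x)) x <- as.list(x)  # vector of file paths
  lapply(x, as_genome_seqs, what = what)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unique canonical k-mers of a genome collection
#'
#' Union of all distinct canonical k-mers over every sequence in the
#' collection, sorted lexicographically.
#'
#' @param genomes sequences: a character vector, a data.frame with a
#'   `seq` column, a `DNAStringSet`, or a FASTA file path.
#' @param k k-mer length (1-32).
#' @return An object of class `kmer_set`: a sorted character vector of
#'   canonical k-mers with attribute `k`.
#' @examples
#' genome_kmer_set("ACGTACGT", k = 4)
#' @export
genome_kmer_set <- function(genomes, k) {
  check_k_param(k)
  g <- as_genome_seqs(genomes)
  if (length(g$seqs) == 0L) stop_param("genome collection is empty")
  new_kmer_set(cpp_unique_kmers(g$seqs, as.integer(k)), k)
}

new_kmer_set <- function(kmers, k) {
  structure(as.character(kmers), k = as.integer(k), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d canonical %d-mers\n", length(x), attr(x, "k")))
  if (length(x)) cat(" ", paste(utils::head(x, 5), collapse = " "),
                     if (length(x) > 5) "..." else "", "\n")
  invisible(x)
}

new_kmer_panel <- function(kmers, k, taxon, rank, provenance) {
  structure(list(taxon = taxon, rank = rank, k = as.integer(k),
                 kmers = sort(unique(as.character(kmers))),
                 provenance = provenance),
            class = "kmer_panel")
}

#' @export
print.kmer_panel <- function(x, ...) {
  cat(sprintf("kmer_panel '%s' (rank %s): %d canonical %d-mers\n",
              x$taxon, x$rank, length(x$kmers), x$k))
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  if (length(x$kmers) == 0L) cat("  [empty panel]\n")
  invisible(x)
}

#' Build a genus-specific k-mer panel
#'
#' A genus-specific k-mer is present in *every* target genome and absent
#' from *all* non-target genomes: the panel is the intersection of the
#' per-target-genome canonical k-mer sets minus the union of all
#' non-target k-mer sets. Only k-mers conserved across the whole target
#' clade and unseen anywhere else survive, which is what makes them
#' usable as genus-level detection markers.
#'
#' @param target_genomes list of genomes (each one genome: FASTA path,
#'   character vector of sequences, or data.frame); a character vector of
#'   file paths is treated as one genome per file.
#' @param nontarget_genomes genomes whose k-mers are subtracted; same
#'   forms accepted; may be empty.
#' @param k k-mer length (default 32, the length that maximizes the
#'   number of specific markers from plastid genomes).
#' @param taxon label for the panel (e.g. a genus name).
#' @return A `kmer_panel` object (taxon, rank = "genus", sorted canonical
#'   k-mers, provenance).
#' @examples
#' build_genus_panel(list("ACGTACGT", "TACGTACG"),
#'                   list("AAACGTAA"), k = 4, taxon = "demo")
#' @export
build_genus_panel <- function(target_genomes, nontarget_genomes = list(),
                              k = 32, taxon = "target") {
  check_k_param(k)
  targets <- as_genome_list(target_genomes, "target genome")
  if (length(targets) == 0L) stop_param("at least one target genome is required")
  nontargets <- as_genome_list(nontarget_genomes, "non-target genome")

  sets <- lapply(targets, function(g) cpp_unique_kmers(g$seqs, as.integer(k)))
  panel <- Reduce(intersect, sets)
  for (g in nontargets)
    panel <- setdiff(panel, cpp_unique_kmers(g$seqs, as.integer(k)))

  prov <- c(sprintf("target: %s", vapply(targets, `[[`, "", "label")),
            sprintf("non-target: %s", vapply(nontargets, `[[`, "", "label")),
            sprintf("op: intersect(%d targets) - union(%d non-targets), k=%d",
                    length(targets), length(nontargets), k))
  new_kmer_panel(panel, k, taxon, "genus", prov)
}

#' Build a species-specific k-mer panel
#'
#' A species-specific k-mer is present in the focal species' genome but
#' absent from its congeneric sibling species and from all other
#' non-target genomes: panel = set(species) - union(siblings) -
#' union(non-targets).
#'
#' @param species_genome the focal species genome (FASTA path, character
#'   sequences, or data.frame).
#' @param sibling_genomes congeneric species genomes to subtract.
#' @param nontarget_genomes all other genomes to subtract.
#' @inheritParams build_genus_panel
#' @return A `kmer_panel` with rank = "species".
#' @export
build_species_panel <- function(species_genome, sibling_genomes = list(),
                                nontarget_genomes = list(), k = 32,
                                taxon = "species") {
  check_k_param(k)
  sp <- as_genome_seqs(species_genome, "species genome")
  if (length(sp$seqs) == 0L || all(nchar(sp$seqs) == 0L))
    stop_param("species genome is empty")
  siblings <- as_genome_list(sibling_genomes, "sibling genome")
  nontargets <- as_genome_list(nontarget_genomes, "non-target genome")

  panel <- cpp_unique_kmers(sp$seqs, as.integer(k))
  for (g in c(siblings, nontargets))
    panel <- setdiff(panel, cpp_unique_kmers(g$seqs, as.integer(k)))

  prov <- c(sprintf("species: %s", sp$label),
            sprintf("sibling: %s", vapply(siblings, `[[`, "", "label")),
            sprintf("non-target: %s", vapply(nontargets, `[[`, "", "label")),
            sprintf("op: species - union(%d siblings) - union(%d non-targets), k=%d",
                    length(siblings), length(nontargets), k))
  new_kmer_panel(panel, k, taxon, "species", prov)
}

#' Filter a panel against confounder read sets
#'
#' Removes every panel k-mer observed at or above `removal_min_freq`
#' times in any single confounder read set (whole-genome sequencing
#' reads of non-target species). This second filtering stage catches
#' k-mers shared with nuclear or mitochondrial sequence of close
#' relatives, which plastid-only subtraction cannot see. Thresholding is
#' per read set, not pooled. The panel can only shrink.
#'
#' @param panel a `kmer_panel`.
#' @param read_sets list of read sets: FASTQ file paths or data.frames
#'   with a `seq` column (as from [read_fastq()]).
#' @param removal_min_freq occurrences within one read set at which a
#'   panel k-mer is discarded (default 1: a single observation removes
#'   it -- the strictest specificity setting).
#' @return The filtered `kmer_panel`, provenance extended with one entry
#'   per read set.
#' @export
filter_panel_with_reads <- function(panel, read_sets, removal_min_freq = 1) {
  check_panel(panel)
  if (!is.numeric(removal_min_freq) || removal_min_freq < 1)
    stop_param("removal_min_freq must be an integer >= 1")
  if (is.data.frame(read_sets) || (is.character(read_sets) && length(read_sets) == 1L))
    read_sets <- list(read_sets)
  kmers <- panel$kmers
  for (i in seq_along(read_sets)) {
    rs <- read_sets[[i]]
    label <- if (is.character(rs) && length(rs) == 1L) rs else
      sprintf("<in-memory read set %d>", i)
    reads <- as_read_seqs(rs)
    if (length(kmers) > 0L && length(reads) > 0L) {
      res <- cpp_count(kmers, reads, panel$k)
      kmers <- kmers[res$count < removal_min_freq]
    }
    panel$provenance <- c(panel$provenance,
      sprintf("filter: %s (removal_min_freq=%d) -> %d k-mers kept",
              label, as.integer(removal_min_freq), length(kmers)))
  }
  panel$kmers <- kmers
  panel
}

as_read_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_fastq(x)
  if (is.data.frame(x)) return(as.character(x$seq))
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x)) return(x)
  stop_param("read set must be a FASTQ path, data.frame or character vector")
}

check_panel <- function(panel) {
  if (!inherits(panel, "kmer_panel")) stop_param("expected a kmer_panel object")
  invisible(TRUE)
}
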