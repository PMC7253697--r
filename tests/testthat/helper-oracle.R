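# Independent naive string-based oracle. Deliberately avoids the 2-bit
# kernel: reverse complement via chartr + string reversal, window
# enumeration via substring(), set algebra on character vectors.

o_rc <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
}

o_canonical <- function(x) {
  if (length(x) == 0L) return(character(0))
  r <- o_rc(x)
  ifelse(x <= r, x, r)
}

# all windows of length k with only A/C/G/T, canonicalized, with 1-based pos
o_extract <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(), kmer = character()))
  pos <- seq_len(n - k + 1L)
  win <- substring(seq, pos, pos + k - 1L)
  ok <- grepl("^[ACGT]+$", win)
  data.frame(pos = pos[ok], kmer = o_canonical(win[ok]),
             stringsAsFactors = FALSE)
}

o_kmer_set <- function(seqs, k)
  sort(unique(unlist(lapply(seqs, function(s) o_extract(s, k)$kmer))))

# targets: list of character vectors (one genome each); nontargets: list
o_genus_panel <- function(targets, nontargets, k) {
  sets <- lapply(targets, o_kmer_set, k = k)
  panel <- Reduce(intersect, sets)
  for (g in nontargets) panel <- setdiff(panel, o_kmer_set(g, k))
  sort(panel)
}

o_species_panel <- function(species, siblings, nontargets, k) {
  panel <- o_kmer_set(species, k)
  for (g in c(siblings, nontargets)) panel <- setdiff(panel, o_kmer_set(g, k))
  sort(panel)
}

# total occurrences of each panel k-mer across all reads (double-strand
# scan realized by canonicalizing every window)
o_count <- function(panel, reads, k) {
  wins <- unlist(lapply(reads, function(s) o_extract(s, k)$kmer))
  tab <- table(factor(wins, levels = panel))
  as.integer(tab)
}

# random test sequences
rand_seq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
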