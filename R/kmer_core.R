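#' Reverse complement of k-mers
#'
#' Watson-Crick reverse complement of each k-mer. The operation is an
#' involution: applying it twice returns the input.
#'
#' @param kmers character vector of k-mers over A/C/G/T (case-insensitive;
#'   each at most 32 bases).
#' @return Character vector of reverse-complemented k-mers, uppercase.
#' @examples
#' reverse_complement(c("AAAA", "ACGT", "GATTACA"))
#' @export
reverse_complement <- function(kmers) {
  kmers <- as.character(kmers)
  tryCatch(cpp_revcomp(kmers), error = function(e) stop_param("%s", conditionMessage(e)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller
#' (A < C < G < T) of the k-mer and its reverse complement. It is the
#' strand-neutral representative used everywhere in this package:
#' panels store canonical k-mers and query windows are canonicalized
#' before lookup, so matching is independent of read orientation.
#'
#' @inheritParams reverse_complement
#' @return Character vector of canonical k-mers, uppercase.
#' @examples
#' canonical_kmer(c("TACG", "CGTA", "ACGT"))
#' @export
canonical_kmer <- function(kmers) {
  kmers <- as.character(kmers)
  tryCatch(cpp_canonical(kmers), error = function(e) stop_param("%s", conditionMessage(e)))
}

#' Extract canonical k-mers from a sequence
#'
#' Slides a window of length `k` along the sequence and reports the
#' canonical k-mer of every window made only of A/C/G/T (after
#' uppercasing). Windows containing any other character (N, IUPAC
#' ambiguity codes, gaps) are skipped entirely; no expansion is
#' attempted. Positions are 1-based window starts on the given strand.
#'
#' @param seq a single nucleotide sequence (character scalar).
#' @param k k-mer length, between 1 and 32.
#' @return A data.frame with columns `pos` (integer) and `kmer`
#'   (character, canonical); zero rows when the sequence is shorter
#'   than `k` or no clean window exists.
#' @examples
#' extract_canonical_kmers("ACGTA", k = 3)
#' @export
extract_canonical_kmers <- function(seq, k) {
  check_k_param(k)
  if (length(seq) != 1L || is.na(seq))
    stop_param("seq must be a single non-NA character string")
  res <- cpp_extract(as.character(seq), as.integer(k))
  data.frame(pos = res$pos, kmer = res$kmer, stringsAsFactors = FALSE)
}

#' Encode / decode k-mers as 2-bit integers
#'
#' Each base maps to 2 bits (A=0, C=1, G=2, T=3) with the 5' end in the
#' most significant bits, so one 64-bit word holds any k-mer up to
#' k = 32 and numeric order on codes equals lexicographic order on the
#' strings. Codes are returned as decimal strings because R has no
#' native 64-bit integer type.
#'
#' @inheritParams reverse_complement
#' @return `encode_kmer`: character vector of decimal codes.
#' @examples
#' decode_kmer(encode_kmer("ACGT"), k = 4)
#' @export
encode_kmer <- function(kmers) {
  tryCatch(cpp_encode(as.character(kmers)),
           error = function(e) stop_param("%s", conditionMessage(e)))
}

#' @rdname encode_kmer
#' @param codes character vector of decimal codes as produced by
#'   `encode_kmer`.
#' @param k k-mer length the codes were produced with.
#' @return `decode_kmer`: character vector of k-mer strings.
#' @export
decode_kmer <- function(codes, k) {
  check_k_param(k)
  cpp_decode(as.character(codes), as.integer(k))
}

check_k_param <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < 1 || k > 32)
    stop_param("k must be a single integer between 1 and 32")
  invisible(TRUE)
}
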