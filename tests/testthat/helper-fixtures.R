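# Programmatic fixtures: temp FASTA/FASTQ writers built from data in code.

tmp_fasta <- function(seqs, ids = sprintf("seq_%d", seq_along(seqs)),
                      gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fasta.gz" else ".fasta")
  write_fasta(data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
              path)
  path
}

tmp_fastq <- function(seqs, quals = strrep("I", nchar(seqs)),
                      ids = sprintf("read_%d", seq_along(seqs)),
                      gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  write_fastq(data.frame(id = ids, seq = seqs, qual = quals,
                         stringsAsFactors = FALSE), path)
  path
}

read_df <- function(seqs, quals = strrep("I", nchar(seqs)))
  data.frame(id = sprintf("read_%d", seq_along(seqs)), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
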