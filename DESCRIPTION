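Package: kmerpanel
Title: Taxon-Specific k-mer Panels for Alignment-Free Detection of Plant
    Taxa in Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs taxon-specific k-mer marker panels from collections of
    plastid (chloroplast) genome sequences by set algebra on canonical
    k-mers, filters panels against confounder whole-genome sequencing read
    sets, counts panel k-mers directly in FASTQ reads or assembled genomes,
    and calls taxon presence against calibrated detection thresholds.
    Includes a synthetic-data module that simulates target clades,
    divergent non-target genomes and error-bearing short-read mixtures so
    the full pipeline is testable without external downloads, plus a
    command-line interface covering panel construction, read trimming,
    detection, subsampling sensitivity curves and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
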