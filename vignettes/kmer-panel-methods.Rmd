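---
title: "Designing and using taxon-specific k-mer panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and using taxon-specific k-mer panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerpanel)
```

## The model

The package detects a plant taxon in shotgun sequencing reads without
alignment, by exact matching against a curated set of taxon-specific
k-mers derived from plastid genomes. The approach rests on three
assumptions:

* **High copy number.** Plastid genomes are present at hundreds of
  copies per cell, so even very shallow whole-genome sequencing
  ("genome skimming", nuclear coverage well below 1x) samples the
  plastid densely enough for k-mer detection.
* **Conservation within, divergence between.** A genus-specific marker
  must be present in *every* available target genome (an intersection
  across genomes) and absent from *all* non-target genomes (subtracting
  their union). Species markers start from a single genome and
  additionally subtract congeneric siblings. Only this
  intersection-minus-union reading produces markers shared by the whole
  target clade; treating the target side as a union would admit
  k-mers private to one species.
* **Exact matching is enough.** With k = 32 and thousands of markers,
  a read either contains a marker verbatim or it does not; sequencing
  errors destroy matches (lowering sensitivity slightly) far more often
  than they create them (inflating specificity), and the asymmetry is
  handled by frequency cutoffs and presence thresholds rather than by
  approximate matching.

All k-mers are **canonical**: the lexicographically smaller of the
k-mer and its reverse complement (A < C < G < T). Panels store canonical
k-mers and every query window is canonicalized before lookup, so
matching is symmetric in read orientation. Whether the original
counting tools canonicalize at list-building time or count both strand
forms separately is immaterial for panel membership and for
detected-k-mer counts at cutoff 1; per-strand occurrence counts would
differ, and we chose the symmetric convention because it is the
simplest one that makes strand invariance a provable property (it is
asserted as a test: counting reverse-complemented reads gives
identical tables).

Internally a k-mer is a 2-bit-per-base unsigned 64-bit integer (A=0,
C=1, G=2, T=3, 5' end in the most significant bits). This caps k at 32
— which is also the default and recommended value, chosen in the
original design to maximize the number of specific markers — and makes
numeric order on codes equal lexicographic order on strings, so panels
sorted numerically are diffable text files.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 32 | marker length, bases; panel-level constant, 1–32 |
| `removal_min_freq` | 1 | occurrences in one confounder read set that remove a panel k-mer |
| `min_freq` | 1 | occurrences in the sample for a k-mer to count as detected |
| threshold | per taxon | detected k-mers needed to call presence (inclusive) |
| trim quality | 35 | Phred score; 3' bases below it are cut |
| trim min length | 32 | reads shorter after trimming are discarded |
| subsample sizes | 1e3 … 1e8 | read-depth grid for sensitivity curves |

Notes on the choices:

* `removal_min_freq = 1` is the strictest specificity setting: a single
  observation of a panel k-mer in a confounder read set removes it. The
  filtering script this emulates used unpublished defaults, so the
  value is configurable; filtering is applied per read set, not pooled,
  because each confounder species is a separate evidence source.
* `min_freq = 2` is the preset used for taxa whose panels are counted
  conservatively (singletons discarded as probable sequencing errors);
  it is configuration, not hard-coded logic.
* The built-in presence thresholds (genus *Lupinus* 1,500 of 31,179;
  *L. albus* 7,500 of 17,091; *L. luteus* 4,000 of 19,857;
  *L. westianus* 4,300 of 11,201) sit above the worst cross-detection
  observed in 1e8-read data sets of close non-target legumes. They are
  defaults in a lookup table and always overridable; an unknown taxon
  with no explicit threshold is an error rather than a guess.
* Trimming reproduces `fastq_quality_trimmer -t 35 -l 32`: cut 3' bases
  while below the quality threshold, stop at the first base at or above
  it (even if worse bases remain further 5'), then discard reads
  shorter than 32 so every kept read can contain one full default-length
  marker. Qualities are Phred+33 only; Phred+64 is rejected, not
  auto-detected.

## What the simulator emulates — and what it does not

`sim_config()` defaults define a fixed desk-scale world: 20 kb genomes
(an order of magnitude below a real plastid genome), 3 target genomes
at 0.5% divergence from a common ancestor (congeneric plastid scale),
7 non-targets at 5% (family scale), 85 bp single-end reads (short-read
single-end scale), substitution errors at 0.001/base (a typical modern
Illumina substitution rate; the value is our choice, stated once here),
constant quality 38. `simulate_mixture()` draws each read from the
target genome with probability `target_fraction`, emulating a spike-in
dilution series of target flour in a background sample; the fraction
maps directly to expected read counts because mixing happens at the
read level.

The error model is substitution-only, because exact k-mer matching is
insensitive to the distinction between an indel and the run of
mismatched windows it would shift; indels would only change *which*
windows break, not how many. Not emulated: real plastid gene content
and structure, coalescent genealogies, platform quality profiles, PCR
duplicates, paired-end structure. Consequently a green simulation test
establishes the correctness of the set algebra, counting, thresholding
and subsampling machinery under the stated divergence/error model — it
does not validate the biological specificity of any real panel, which
depends on the completeness of the genome databases used to build it.

Genomes are linear by default. `simulate_reads(circular = TRUE)` wraps
reads around the origin, as on the circular plastid chromosome; this
removes the linear edge effect in which a window near the sequence end
is covered by almost no read placements. The full-recovery acceptance
test uses the circular mode because its coverage argument (recovered
fraction approaching 1 near 20x) assumes uniform window coverage.
`random_genome(inverted_repeat = n)` optionally appends a
reverse-complemented terminal segment, mimicking the plastid inverted
repeat; because the copy is a reverse complement, it adds no new
canonical k-mers beyond the junction windows.

## Numerical and procedural choices

* **Set algebra** is performed on sorted unique canonical k-mer string
  vectors produced by the compiled extractor; panels are stored sorted,
  so construction is order-independent (asserted property) and output
  is reproducible byte-for-byte.
* **Ambiguity:** any window containing a non-ACGT character is skipped
  whole; no IUPAC expansion. This is conservative in both directions
  (an ambiguous genome position contributes no marker; an ambiguous
  read position detects none).
* **Multi-record FASTA:** one *file* is one genome for intersection
  purposes; records within a file are unioned, because assemblies may
  be multi-contig. Non-target files are unioned anyway, so the choice
  only matters on the target side.
* **Subsampling** uses a single seeded permutation and takes prefixes:
  subsets are nested, so sensitivity curves are non-decreasing
  deterministically, not merely in expectation as with independent
  subsets. The permutation seed is explicit everywhere.
* **Inclusive comparisons** throughout: detected means count ≥
  `min_freq`; present means detected ≥ threshold ("at least").
* **Degenerate inputs:** an empty genome collection is an error, but a
  genome that happens to contain no clean window yields an empty set; an
  empty panel is representable and serializable (flagged on print) but
  cannot be counted against; reads shorter than k contribute nothing and
  an all-short read set produces an all-zero table with a warning.
* **FASTQ parsing** is a strict four-line reader written here rather
  than delegated: the available permissive reader pads a short quality
  string instead of failing, and the contract requires failing with the
  record ordinal.

## Known limitations

* Saturation: once the target's window coverage in a sample exceeds
  roughly 10x, every detectable panel k-mer is seen, and detected
  counts stop discriminating between target fractions (the acceptance
  suite documents one deliberately failing strict-increase assertion at
  exactly this plateau; real dilution series show the same flattening at
  their top concentrations). Quantitative abundance estimation is out of
  scope.
* Panels are only as specific as the genome collections they are built
  from; k-mers private to an unsequenced relative will leak. The
  read-set filtering stage mitigates but cannot eliminate this.
* k > 32 is unsupported by design (single-word encoding).
* Pairs are treated as independent single-end reads; per-k-mer genomic
  coordinates are not tracked.

## A compact end-to-end run

```{r example, eval = FALSE}
cfg   <- sim_config(genome_length = 5000, n_reads = 20000,
                    target_fraction = 0.005, seed = 11)
clade <- simulate_clade(cfg)
panel <- build_genus_panel(as.list(clade$targets),
                          as.list(clade$nontargets),
                          k = 32, taxon = "sim-clade")
mix   <- simulate_mixture(cfg, clade)
res   <- detect_taxon(panel, mix$reads, min_freq = 1, threshold = 100,
                      trim = FALSE)
res$call
curve <- sensitivity_curve(panel, mix$reads, c(1000, 5000, 20000),
                           seed = 1)
```

With seed 11 this produces a 570-k-mer panel, detects 346 of them at a
0.5% target fraction (called present against the explicit threshold
100), and yields a monotone curve (61, 167, 346 detected k-mers at
1,000 / 5,000 / 20,000 reads) — numbers printed by the README example
and re-derivable from the code above.
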