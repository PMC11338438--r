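---
title: "Isoform-resolved annotation of transcript-mapped RNA features: methods and design"
author: "txmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txmeta methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmeta)
```

## The problem

Long-read sequencing assigns RNA features — chemical modifications such as
m6A, structured regions, protein-binding sites — to individual transcript
isoforms, in the transcript's own coordinate system. Two things are then
routinely needed: the genomic coordinates of those features (for genome
browsers and interval tooling), and their position relative to transcript
landmarks (UTR/ORF boundaries, splice junctions, start and stop codons),
computed *on the isoform the feature was called on*. The second point is
what distinguishes this package from conventional metagene tools that
collapse all features of a gene onto a single representative transcript: a
single genomic position can lie in the 3'UTR of one isoform and in the CDS
of another, with different expected biology in each.

`txmeta` implements both steps as composable table transforms plus a set of
profile summaries and plots, driven by a GTF2 gene annotation.

## Coordinate model

* GTF input is 1-based inclusive; BED-style input and output and every
  exported coordinate are 0-based half-open. Transcript position 0 is the
  5'-most transcribed base; for minus-strand isoforms that is the highest
  genomic coordinate of the 5'-most exon.
* A `TranscriptModel` stores the exon chain in transcript order with its
  cumulative lengths, so transcript-to-genome mapping is a binary search
  (`findInterval`) over cumulative exon lengths followed by an offset into
  one exon; genome-to-transcript is the inverse and returns `NA` off-exon.
  Exon spans are held as plain integer vectors (the `exons()` accessor
  materialises a `GRanges`) so that a 5,000-isoform annotation builds in
  about a second.
* The ORF span is the union of a transcript's CDS records extended by its
  stop_codon records (Ensembl GTF dialect): `cdsTxEnd()` is the final
  stop-codon base, and "ORF" in all outputs includes the stop codon. Region
  lengths always satisfy 5'UTR + ORF + 3'UTR = transcript length.

## Liftover

Each BED3+ record (`transcript`, `start`, `end`, free extra columns) maps
through the exon chain of its named isoform. The output is BED6+n: genomic
`chrom`/`start`/`end`, `name` = the source transcript id, `score` = `"."`,
`strand`, followed by *every* input column byte-for-byte — stripping the
first six output columns reconstructs the input file exactly. Records whose
transcript is missing from the annotation are skipped (or abort, on
request) and counted; records whose ends fall on different exons are
emitted as a single interval spanning the intron(s), with a warning and a
counter, rather than as blocked BED12 — the motivating use case is
single-nucleotide sites, and one-record-in/one-record-out keeps the
lossless contract simple. Input strand columns, if present among the
extras, are ignored for mapping (transcript coordinates are plus-strand by
definition) but preserved.

## Annotation

`annotateSites()` appends 12 columns: `gene_id`, `gene_name`,
`transcript_biotype`, `tx_len`, `cds_start`, `cds_end`,
`transcript_metacoordinate`, `abs_cds_start`, `abs_cds_end`,
`up_junc_dist`, `down_junc_dist`, `tx_end_dist`. The representative
position of a multi-base feature is its 5' base. Conventions that were
genuinely open and the choices made:

* **Metacoordinate.** Position `p` on a coding isoform with region lengths
  `(L5, Lc, L3)` maps to `p/L5` in the 5'UTR, `1 + (p−L5)/Lc` in the ORF,
  `2 + (p−L5−Lc)/L3` in the 3'UTR. `floor()` of the value identifies the
  region; the first ORF base is exactly 1 and the first 3'UTR base exactly
  2. With 0-based positions the final base maps strictly below 3;
  we treat the conventional "(2–3]" notation as descriptive, not as a
  requirement that 3.0 be attained. Noncoding isoforms get `NA`.
* **Junction distances** are 1-anchored on both sides: the bases
  immediately flanking a junction have distance 1 upstream and 1
  downstream, keeping the two sides symmetric. `NA` means no junction
  exists on that side; single-exon transcripts are `NA`/`NA`.
* **Codon distances** are signed nt offsets (negative = 5' of the
  landmark) to the first ORF base and the last stop-codon base, so
  `abs_cds_end − abs_cds_start = −(orf_len − 1)` always.
* **`tx_end_dist`** (`tx_len − 1 − p`) rounds out the landmark set with
  the distance to the transcript's final base.
* `NA` is serialised literally as `NA`; metacoordinates print with 4
  decimals so adjacent bases on long transcripts remain distinguishable.

## Profiles, trends, plots

Sites are classed positive by a simple predicate (column, comparator,
threshold — e.g. stoichiometry `> 10`); records with non-numeric values in
the filter column are dropped from numerator *and* denominator and
counted. Three profile summaries share one table shape (`axis_value`,
`n_positive`, `n_total`, `proportion`):

* **Metatranscript**: 120 bins of width 0.025 across [0,3] (bin =
  `floor(meta/width)` clamped to the last bin; midpoints plotted).
* **Metajunction**: 1-nt offsets from each site's *nearest* junction,
  upstream and downstream panels, default window 300 nt — wide enough to
  show context around the ~200-nt junction-proximal depletion zone
  reported for m6A.
* **Metacodon**: 1-nt signed offsets from the start or stop codon,
  default window 100 nt.

Trends are ordinary `stats::loess` fits (degree 2, direct surface) of
proportion on axis value, with a pointwise 95% band as fit ± 1.96 standard
errors. Defaults: span 0.3 for the 120-bin metatranscript axis, 0.5 for
the noisier 1-nt profiles; both exposed as arguments/flags. Fewer than 10
usable bins skips the trend (points-only plot) rather than fitting an
unstable curve. Fits are clipped to [0,1] for display only; the raw fit is
retained in the returned table. Every plot writes its underlying table as
TSV alongside the image, so figures are re-plottable and diffable.

## The synthetic-data generator

`simulateTranscriptome()` tiles genes along one virtual chromosome
(`chrS`, 1000-nt gaps). Isoforms of a gene share the gene's exon chain but
draw independent UTR boundaries, which guarantees (for multi-isoform
genes) genomic positions whose region differs between isoforms — the
scenario that motivates isoform-resolved annotation. Defaults (1–8 exons
of 80–400 nt, introns 100–2000 nt, 5'UTRs 10–300 nt, 3'UTRs 50–500 nt,
half of genes on each strand, 10% noncoding isoforms) were chosen once as
plausible mRNA-scale values. `simulateSites()` draws sites uniformly, with
a junction-proximal depletion zone (default 200 nt, positive rate 0 inside
vs 0.30 outside, mirroring the reported m6A exclusion around junctions),
or with positives placed around a codon offset. Stoichiometry percentages
are drawn above/below the 10% threshold according to the true label, so
filtering at `> 10` recovers the labels exactly.

The companion truth table is computed by naive per-base enumeration of
each exon chain and explicit minimisation over junction lists —
deliberately independent of the package's mapping arithmetic — and serves
as the oracle in the test suite. What the generator does **not** emulate:
sequence context (no DRACH motifs), read-level error, coverage-dependent
stoichiometry noise, overlapping genes, or multi-chromosome annotations.
Passing tests therefore demonstrate coordinate/bookkeeping correctness and
shape recovery, not robustness to basecaller noise in real nanopore data.

For depletion-recovery checks the fixtures use 2–5 exons of 500–1500 nt so
that a substantial fraction of sites lies farther than 200 nt from any
junction on both sides; with short exons nearly every site is
junction-proximal and the "outside" baseline is undersampled.

## Numerical and degenerate-input choices

* Zero-length UTRs are legal (`metacoordinate(c(0, L, 0), 0)` is exactly
  1); a position can never fall inside an empty region.
* Transcripts with CDS but no exon records, or with overlapping exons, are
  skipped with a warning and counted, not fatal.
* Version-stripped transcript lookup (`.N` suffixes) is opt-in and errors
  on ambiguity, listing the candidates.
* Bins with zero tested sites report `NA` proportion and are excluded from
  trend fitting; empty profile tables refuse to plot.
* Problem sizes in the tests were chosen to exercise the full pipeline at
  a realistic desk scale (about 5,200 isoforms from 2,600 genes and 10,000
  sites for the end-to-end run; 100+ random transcripts for exhaustive
  per-base oracle comparisons; 6,000 sites for depletion recovery).

## Known limitations

* Junction-spanning features are emitted as one intron-spanning interval,
  not blocked BED12.
* One annotation at a time; no GFF3; no genome FASTA access.
* The metajunction profile keys each site only to its nearest junction on
  each side, so a site between two close junctions contributes to both
  sides but to no farther junction.
* Whether a reference implementation would report `meta = 3.0` at the last
  transcript base, or anchor junction distances at 0, are convention
  choices documented above rather than universally standardised.
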