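---
title: "Validating CRISPR knockouts from alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating CRISPR knockouts from alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceko)
```

## The problem

Injecting CRISPR/Cas9 into embryos of a non-model organism produces F0
founders that are *mosaic*: different cells carry different repair
outcomes at the target site, and some cells remain wild type. Before any
phenotype can be attributed to a knockout, three questions must be
answered from sequencing data alone:

1. **What alleles does each individual carry, and in what proportion?**
   Amplicon (e.g. Sanger-clone) reads over each target site are
   genotyped read by read, and the mutant-allele fraction summarises the
   mosaicism.
2. **Do the observed indels actually break the gene?** Each indel is
   classified as loss-of-function (LOF), splice-site (SS) or in-frame
   (IF) against a transcript model.
3. **Did splice-site indels really cause exon skipping?** RNA-seq
   junction reads quantify, per individual, the percentage of
   transcripts that retain the exon adjacent to the target site.

spliceko implements these three analyses downstream of read mapping
(bwa for amplicons, a spliced aligner for RNA-seq are assumed upstream),
plus the counts-per-million expression floor commonly applied before
differential expression, and a seeded simulator that generates all
inputs in standard formats. A typical use case is verifying a fish gene
knockout — say a fatty-acid elongase such as *elovl2* — where guides
land near intron–exon boundaries and aberrant splicing is the suspected
mechanism.

## Coordinates and the gene model

All internal coordinates are **1-based, fully closed**, the convention
of IRanges/GenomicRanges, GFF3 and SAM alike. Because every format this
package reads or writes already uses that convention, no conversion
happens anywhere, which removes the usual off-by-one ambiguity at
interval boundaries. An indel is anchored VCF-style at the base
*before* the event, so a deletion at anchor $p$ of length $L$ removes
bases $p+1,\dots,p+L$.

A `transcript_model` holds exons and CDS in genomic order and derives
introns as the gaps between consecutive exons; exon *ordinals*
(including the exon-of-interest index for retention analysis) are
counted in transcript orientation, so ordinal 1 is the 5'-most exon of
the mRNA also on the minus strand. When several transcripts exist per
gene, the caller names one explicitly — no canonical-transcript
heuristic. Reading frame is derived from CDS interval lengths alone;
GFF3 `phase` attributes are validated when present but not required.

## Indel extraction and mosaicism

Indels are read directly off the CIGAR string: M/=/X consume reference
and query, D and N reference only, I and S query only, H neither; every
I or D operation becomes a call at the cumulative reference position. N
operations are spliced introns and never become calls.

Three rules keep per-individual tallies honest:

* **Spanning criterion** (`min_flank`, default 5 bp): a read is
  genotypable only if its aligned span covers the whole target window
  plus the flank on both sides. A read clipped inside the window can
  neither prove nor exclude an indel, so it is dropped from both the WT
  and the mutant count rather than inflating the WT tally.
* **Left normalisation**: when the reference is supplied, indels are
  shifted to their leftmost equivalent representation (deletions slide
  while the base before equals the base after the deleted block;
  insertions rotate analogously). Identical alleles observed on
  different reads then share one key.
* **Composite alleles**: all indels on one read form a single allele
  key — a clone carrying two indels is one allele, not two.

The mosaic mutant fraction is $1 - n_\mathrm{WT}/n_\mathrm{total}$ over
genotypable reads. No KO/WT threshold is applied: with a handful of
clones per individual the fraction itself is the honest summary, and
cut-offs belong to the caller.

## Consequence classification

Each indel receives exactly one of three categories, with precedence
**SS > LOF > IF**:

1. **SS** — the indel's reference footprint (for insertions, the anchor
   base) overlaps a splice-site window: `intronic_bp` (default 8) bases
   into the intron and `exonic_bp` (default 3) bases into the exon at
   any exon/intron junction, the window convention of the SnpEff
   annotator family. The canonical GT/AG dinucleotides are always
   included even if `intronic_bp` is set below 2. The reason
   distinguishes a hit on the canonical donor/acceptor bases from the
   flanking `splice_region`.
2. **LOF** — the net CDS-length change is not a multiple of 3
   (frameshift), or the deletion removes more than 50% of the coding
   sequence. Deletions count the coding bases they overlap; an
   insertion contributes its full length when anchored inside the CDS.
3. **IF** — everything else. Indels outside both the transcript span
   and all splice windows are additionally flagged `noncoding` rather
   than silently categorised.

The precedence makes the three categories mutually exclusive, so
per-site histograms add up to the number of unique indels. Summaries
deduplicate by allele key by default (the same deletion seen in five
clones counts once); counting reads instead is one flag away. For
composite alleles, `classify_indels(..., by_allele = TRUE)` decides
frameshift from the *summed* net CDS change of the read's indels, since
a +1 insertion and a −1 deletion on the same molecule restore the frame.

## Percentage exon retention (PIR)

For an internal exon of interest (Eoi) with upstream neighbour E3 and
downstream neighbour E5 (transcript orientation), junction-spanning
reads are counted in three classes: E3–Eoi, Eoi–E5, and E3–E5 (the
exclusion reads that skip the Eoi). Then

$$
\mathrm{inclusion} = \frac{n_{\mathrm{E3\text{–}Eoi}} + n_{\mathrm{Eoi\text{–}E5}}}{2},
\qquad
\mathrm{PIR} = 100\cdot\frac{\mathrm{inclusion}}{\mathrm{inclusion}+\mathrm{exclusion}} .
$$

Averaging the two inclusion junctions makes the numerator commensurate
with the exclusion count, which has only one junction to be observed
at. Since the arithmetic is symmetric in the two flanking exons, the
upstream/downstream labelling cannot change any result. PIR is `NA`,
not an error, when no informative read exists; terminal exons are
rejected because no skip junction is defined for them.

Counting rules, all configurable:

* A read supports a junction only when one of its N gaps matches the
  corresponding annotated intron (or fused intron pair, for skipping)
  **exactly**, with zero tolerance. Spliced aligners report exact
  junction coordinates, and exactness keeps the three classes mutually
  exclusive.
* At least `min_anchor = 8` aligned bases are required on each side of
  the gap; shorter anchors are too easily misplaced.
* A read spanning both Eoi junctions increments both inclusion counts;
  reads with several gaps are evaluated gap by gap.
* Duplicate, secondary and supplementary records are skipped. Counting
  is per alignment record; no mapping-quality filter is applied by
  default, on the assumption that uniquely mapping reads were selected
  upstream.

## Expression floor

`filter_expressed()` keeps a gene when its counts-per-million reach
`min_cpm = 1` in at least `ceiling(0.25 · n_samples)` samples. Library
sizes are raw column sums — the filter runs before any between-sample
normalisation, as is standard. Because "in 25% of samples" is sometimes
meant strictly, the comparator is exposed
(`comparator = "more_than"` uses `floor(0.25·n) + 1`); the two differ
exactly when `0.25·n` is an integer.

## The synthetic-data generator

`make_toy_locus()` builds a plus-strand gene with equally sized,
equally spaced exons (defaults: 8 exons of 120 bp, 300 bp introns),
random sequence under a fixed seed, GT/AG written at every intron end,
and a CDS covering the exons trimmed to a multiple of 3. Geometry that
cannot support the junction-anchor requirement (exons shorter than
twice `min_anchor`) is rejected at generation time.

`simulate_amplicon_reads()` emits one SAM record per clone, each
covering the target window ± 60 bp. Defaults mirror a realistic
validation design: 8 clones per individual and a mutant-allele fraction
of 0.625. The realised allele composition is **exact** by default
(`round(fraction · n_reads)` mutant reads, identities shuffled):
sampling a few clones from a mosaic at a configured fraction should
realise that fraction, and with n = 8 a Bernoulli draw would rarely do
so. The per-read Bernoulli model remains available as
`composition = "binomial"`. Truth tables (read → allele key) are
first-class outputs, so every downstream result can be checked against
the generating truth.

`simulate_spliced_reads()` draws each fragment's source isoform —
Eoi-included (abundance $1-s$) or Eoi-skipped (abundance $s$) — with
probability proportional to abundance × number of valid read start
positions, the standard length-weighted generative model of short-read
RNA-seq. Plain abundance-proportional draws would bias the junction
estimator by the isoform length difference; under length weighting the
expected PIR equals $100(1-s)$ exactly. Reads (default 100 bp, 4000
fragments) are placed uniformly along the chosen isoform, so junction
anchors of every length occur and the 8 bp filter is genuinely
exercised. With 4000 fragments roughly 500–800 informative junction
reads arise, putting the binomial standard error of PIR below 2
percentage points — the package's property tests assert recovery within
3 points for skip fractions 0–0.9.

What the generator does **not** emulate: sequencing errors and base
qualities, PCR duplicates, paired-end fragment-size structure,
misalignment, multi-isoform mixtures beyond the two-isoform skip model,
and expression differences between individuals. Passing tests therefore
demonstrate the correctness of the counting and classification
arithmetic under clean alignments, not robustness to noisy real data —
on real alignments the upstream mapper's handling of mismatches near
junctions will dominate.

## Numerical and degenerate-input choices

* Zero genotypable reads → mutant fraction `NA` with a `no_reads` flag;
  zero informative junction reads → PIR `NA`. NA is a value, never an
  error.
* Single-exon transcripts have no splice boundaries (empty set, not an
  error); terminal exons are invalid exons-of-interest (error).
* When an indel overlaps both the canonical dinucleotide window and the
  exonic splice region, the canonical reason wins; when it overlaps
  both a splice window and the CDS, the category is SS alone — nothing
  is double-counted.
* Half-integral inclusion counts are kept as-is; no rounding anywhere
  in the PIR arithmetic.
* Simulator output is byte-identical for identical configurations;
  every CLI run writes a provenance record (resolved options, seed,
  versions).

## Limitations

The classifier implements the three-category summary, not a full
variant annotator: no HGVS notation, no start/stop-specific
subcategories, no multi-transcript annotation. The splice-quant module
covers exon skipping only — not alternative donors/acceptors, genuine
intron retention, or isoform-level quantification. Genotyping is
quality-blind and treats each alignment record as one vote.
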