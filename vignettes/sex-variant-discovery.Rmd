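---
title: "Discovering sex-associated genomic variation from small WGS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-associated genomic variation from small WGS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexvarscan)
```

## The problem

Many fish species, sturgeons among them, have no morphologically or
karyotypically distinguishable sex chromosomes; sex determination is thought
to rest on one or a few short sex-variable genomic regions. With
whole-genome sequencing of a small cohort — five males and five females
mapped to a reference genome — those regions can be searched for as
*genotype patterns*: positions where every male carries a homozygous
alternate call while every female is heterozygous or reference. Because the
cohort is tiny and the genomes of sturgeons are polyploid (the diploid
caller model collapses many true dosages into 0/1 and 1/1), the filtering
has to be deliberately stringent and asymmetric, and the interesting signal
is not individual sites but *clusters* of them.

`sexvarscan` implements that discovery pipeline end to end, together with a
synthetic-cohort generator that plants every category of signal at recorded
coordinates so the whole chain can be validated exactly.

## The discovery model

A merged multi-sample site carries per-sample diploid genotypes and the
usual allele bookkeeping: `AC` (alternate allele count), `AN` (called
alleles, 2 per non-missing sample) and `AF = AC/AN`. All `AF = 1` tests
are made on the integer identity `AC == AN` at full `AN`, never by
floating-point comparison.

Two extractions act on merged sites:

* **Inter-species fixed variants** — sites where all ten cohort samples are
  `1/1` against the reference of a related species (`AF = 1`). These
  measure divergence between the sequenced species and the reference
  species.
* **Sex-associated variants** — sites where (a) all five males are `1/1`
  in *quality-filtered* calls (QUAL strictly greater than 30); (b) every
  female is `0/1`, `0/0`, or has no record in *unfiltered* female calls;
  and (c) read depth is strictly greater than 2 in **all ten** samples at
  the position.

Three asymmetries are intentional and load-bearing:

1. Male records are quality-filtered; female records are not. A
   low-quality female heterozygote is still evidence *against* sex
   association, so discarding it would inflate false positives.
2. A recordless female counts as `0/0` — variant callers emit variant-only
   VCFs, so a reference-homozygous position simply has no record. The
   depth gate (c) exists precisely so that "no record" can be read as
   "reference with coverage" rather than "no data".
3. A female `1/1` at the position — at *any* alternate allele, multi-allelic
   records included — disqualifies the site outright.

Boundary conventions are pinned by tests: QUAL exactly 30 is removed;
depth exactly 2 fails the gate and 3 passes it.

### Clusters, peaks and nearest genes

The genome is scanned in consecutive non-overlapping 10 kb windows
anchored at position 1 of every contig (window index
`floor((pos - 1)/10000)`; the final partial window is retained). A *peak*
is a window holding at least 30 sex-associated variants; the strictly-greater
comparator is also exposed for "more than N"-style summaries. The peak
table reports, per peak, the first and last variant positions inside the
window and the count.

Each peak (or raw variant) is assigned its nearest gene with the
`bedtools closest -d -k 1 -t first` conventions: distance 0 on overlap,
otherwise the gap in base pairs with adjacent features 1 bp apart, ties
broken by the gene that comes first in coordinate-sorted order, strand
ignored. For a 1-based query `p` against a 0-based half-open gene
`[s, e)` the non-overlap distance is `min(|p - (s+1)|, |p - e|)`. Because
one gene can be nearest to two peaks, both the number of peak assignments
and the number of *distinct* gene symbols are reported.

### Sex-exclusive coverage

Independently of genotypes, a position is *sex-exclusive* when every
sample of one sex has depth 0 and at least 3 samples of the other sex have
depth at least 10. "A depth of 10" is read as depth ≥ 10; a strict-equality
reading would be meaningless. The per-direction position lists and the
count of distinct contigs carrying them are reported. Pooled group depth
is the arithmetic *sum* of member depths (pooling alignments), not the
mean, and "covered" means pooled depth at or above a floor that defaults
to 1 (the definition the headline coverage percentages leave unstated; it
is exposed as a parameter).

### Pairwise dN/dS

Ortholog CDS pairs are compared with the Nei–Gojobori (1986) counting
method. Synonymous site counts per codon (summed fractional synonymous
changes over the three positions, mutation-to-stop counted nonsynonymous)
are averaged over the two sequences; differences in multi-difference
codons are averaged with equal weights over all minimal substitution
pathways, excluding pathways through stop-codon intermediates (if every
pathway is blocked, all are used). Proportions are Jukes–Cantor corrected,
`d = -(3/4) ln(1 - (4/3) p)`; `p ≥ 3/4` is reported as saturated rather
than silently dropped. `ω = dN/dS` is classified `> 1` adaptive, `< 1`
purifying, `= 1` neutral, and left `undefined` when `dS = 0` — never
silently purifying. Pairs with `dS` outside `[0.01, 2]` (both boundaries
kept) are too similar or too diverged for a reliable ratio and are
filtered out.

The counting estimator replaces maximum-likelihood codon models
deliberately: the scientific use of the ratio here is classification
against 1 and the `dS` range filter, both of which the counting method
supports while remaining hand-verifiable at the single-codon level
(the three-codon worked pair `TTT GCT AAA` vs `TTC GCT AAA`, with
`S = 5/3`, `pS = 0.6`, `dS = -(3/4) ln 0.2`, is a frozen test). Exact
numeric parity with ML per-gene estimates on real data is expressly not a
goal. Ambiguity codes are rejected rather than guessed at, since pathway
counting is undefined for ambiguous codons; terminal stop codons are
stripped and internal stops are errors.

The codon alignment itself is built by back-translating a protein
alignment and dropping every column in which either protein has a gap
(`pal2nal -nogap` behaviour), with the CDS re-translated and checked
residue-by-residue first.

## What the synthetic cohort emulates

`simulation_config()` describes the study conditions: 2 contigs of
100 kb, 5 males + 5 females, Poisson depth with mean 20 (matching the
17–23× per-sample depth typical of such cohorts), three planted clusters
of 40 sex-associated variants each inside single 10 kb windows, a
5 × 10⁻⁴ per-bp rate of species-fixed sites, a background heterozygous
noise rate of 10⁻⁴ per bp per cohort (≈200 single-sample 0/1 records),
50 low-QUAL decoy sites (male `1/1` with QUAL ≤ 30, the first pinned at
exactly 30 to exercise the strict inequality), one sex-exclusive coverage
block per direction, and about 10% of planted variants emitted as 1 bp
indels so the SNP/indel decomposition has something to count.

Planted categories are pairwise disjoint in (contig, position), and depths
are clamped to ≥ 3 at planted variant sites so the depth gate never erases
planted truth: in the noise-free-female regime recovery is exact by
construction, and the tests assert precision = recall = 1. Passing QUAL
values are drawn in (30, 100], decoys in [0, 30]. Females at planted sex
sites are split 50/50 between explicit `0/1` records and absent records,
because both are equivalent non-association evidence.

The generator does **not** emulate read-level artifacts (mapping bias,
duplicates), linkage between sites, realistic mutation spectra,
multi-nucleotide indels, or polyploid dosage. Passing the planted-recovery
suite therefore demonstrates that the *filters implement their stated
rules exactly*; it says nothing about caller error modes on real data.

Genotypes are diploid-coded throughout even though the motivating organism
is octoploid — this mirrors the diploid caller model the pipeline
consumes, and heterozygous classes necessarily conflate many true dosages.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `min_qual` | 30 | records kept when QUAL > 30 (males / all-sample merges) |
| `min_depth_exclusive` | 2 | sex-site depth gate, strict: depth ≥ 3 in all samples |
| `exclusive_min_depth` | 10 | depth floor in the covered sex for exclusivity |
| `exclusive_min_samples` | 3 | covered-sex samples that must reach the floor |
| `window` | 10,000 bp | segment width, anchored at position 1 per contig |
| `cluster_threshold` | 30 | minimum variants for a peak (`>=` comparator) |
| `ds_lo`, `ds_hi` | 0.01, 2 | inclusive dS plausibility bounds |

All thresholds live in `run_config()` and are passed to stage functions
explicitly; there are no hidden constants.

## Numerical and degenerate-input choices

* Spacing statistics use within-contig consecutive distances only; on an
  unordered draft assembly a cross-contig distance is meaningless. A
  contig with fewer than two variants contributes nothing, and a cohort
  with no pair at all reports an absent (NA) mean rather than zero.
* Per-segment means are reported both including and excluding empty
  windows; the excluding-empty mean is absent when no window has a
  variant.
* Positions with conflicting REF alleles across samples are excluded from
  merges with a logged count; each (contig, pos, ref, alt) key is its own
  site, and multi-allelic VCF records are split per ALT on reading.
* Depth tables must be dense (`samtools depth -aa` layout); gaps,
  duplicates and unsorted rows are format errors naming the offending
  contig and position, so silent coordinate drift is impossible.
* Determinism: every simulation function derives its RNG stream from the
  configured seed; identical configurations produce byte-identical FASTA,
  BED, VCF, depth and truth files, and identical pipeline reports.

## Problem sizes

The shipped defaults exercise the full pipeline on a 200 kb genome with
ten samples in a few seconds; the oracle-equivalence suites run the naive
position-by-position reference implementations on 40–80 kb cohorts, and
the NG86 property tests use 100 random 30–36 bp codon pairs. These sizes
were chosen so an exhaustive brute-force check remains practical; every
statistic is size-free and applies unchanged to multi-Gb inputs.

## Known limitations

* Real-data headline numbers from multi-Gb, ~165× aggregate-coverage
  cohorts (millions of inter-species variants, thousands of sex-associated
  positions) are outside desk scale and are not reproduced here; the
  package reproduces the *rules* and validates them on planted truth,
  plus the worked summaries computable from the published 15-cluster peak
  table shipped in `inst/extdata/`.
* Variant calling and read alignment themselves are out of scope: the
  pipeline consumes per-sample VCFs and depth tables.
* The NG86 estimator ignores transition/transversion bias and codon
  frequencies by design; see above.
* Functional enrichment of candidate gene lists is database-version
  dependent and deliberately not included.
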