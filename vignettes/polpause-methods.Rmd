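---
title: "Quantifying Pol II promoter-proximal pausing from ChIP-seq coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Pol II promoter-proximal pausing from ChIP-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RNA polymerase II frequently initiates, transcribes a few dozen bases, and
then pauses just downstream of the transcription start site (TSS) before
being released into productive elongation. The balance between paused and
elongating polymerase is regulated — CTD phosphatases and kinases shift it —
and it leaves a characteristic footprint in Pol II ChIP-seq: a sharp
promoter-proximal peak, a lower gene-body plateau, and often a second rise
around the transcription end site (TES) where termination is slow.
**polpause** turns aligned ChIP-seq read intervals into the standard
quantitative summaries of that footprint: normalized occupancy tracks,
metagene profiles, per-gene traveling ratios and 3' pausing indices, and
the downstream classification and integration steps (chromatin state from
histone marks, peak annotation, differential-expression overlap) that such
a study needs. A seeded simulator plants known promoter/body/3' structure
so that every stage can be validated against ground truth without any
external data.

## From reads to occupancy tracks

Single-end ChIP-seq reads mark only the 5' end of each immunoprecipitated
fragment. `extend_reads()` grows every read to the expected fragment
length (default 150 bp) in its strand direction, recovering approximate
fragments. `compute_coverage()` accumulates per-base fragment depth,
sums it in consecutive bins (default 20 bp), divides by the bin size and
scales by `1e6 / total_reads` (reads-per-million) times an optional
spike-in factor (`spike_in_factor()` returns `reference / sample` spike
read counts, the vendor convention that rescales each sample to a common
exogenous-chromatin depth).

Two numerical choices matter here:

* **Partial bins.** A bin value is the per-base depth *sum divided by the
  bin size*, which equals the per-base mean for every full bin. For the
  single trailing bin of a chromosome whose length is not a multiple of
  the bin size, bases past the end count as zero depth. This keeps the
  conservation identity
  `sum(bins) * bin_size == norm_factor * sum(fragment_lengths)`
  exact for every input, which the test suite asserts against a per-base
  brute-force oracle on hundreds of random instances.
* **Windows.** `window_density()` is a length-weighted mean of bin values,
  so partially overlapped bins contribute proportionally; it equals a
  per-base average of the track expanded to base resolution.

Normalization by sequencing depth alone is the default. Where an
input-chromatin or total-Pol II reference is available, division happens
explicitly through `normalized_occupancy()`, which computes the bin-wise
pseudocounted ratio `(factor + eps) / (reference + eps)` (default
`eps = 0.1`; 0/0 bins become 1). Keeping depth normalization and
reference division separate makes both interpretations available rather
than baking one into the track.

## Coordinates

All containers are `GRanges`, i.e. the Bioconductor 1-based closed
convention; BED input (0-based half-open) is converted on read by
`read_bed6()`/`read_genes()` and converted back on write, GTF (1-based
closed) passes through unchanged. One convention everywhere avoids
off-by-one drift; the BED half-open semantics survive where they matter
(an interval ending where a blacklist region starts shares no base and is
not an overlap). TSS and TES are always derived from interval plus strand
(`gene_tss()`, `gene_tes()`), never stored, so they cannot go stale.

## Metagene profiles

`gene_signal_vector()` samples a track on the common metagene axis: 200
fixed 20-bp bins covering 4 kb upstream of the TSS, 100 percent-scaled
body bins (each the length-weighted density of one percent of the gene),
and 200 bins covering 4 kb downstream of the TES. Vectors are oriented
5' to 3' regardless of strand. Profile cohorts should be restricted to
genes at least 4 kb from any other annotation
(`select_isolated_genes()`, edge-gap rule) so flanks do not pick up a
neighbour's promoter.

Choices made where the convention is not fixed in the field:

* **Body resolution** is 100 percent bins — a percentage axis with one bin
  per percent; configurable.
* **Flank bins past a chromosome end are missing (`NA`), not zero.**
  Zero-filling would bias cohort means downward near contig edges;
  `aggregate_profile()` averages over the genes that actually have the
  bin.
* **Minimum gene length** equals the body bin count (a gene shorter than
  100 bp cannot fill 100 body bins and is rejected with an error).
* The aggregator is the mean (an "average occupancy plot"); the median is
  exposed for skew-robust profiles.

## Traveling ratio and 3' pausing index

For each gene three strand-oriented windows are defined
(`pausing_windows()`), in transcription-direction coordinates:

* `a` (promoter-proximal): `[-30, +300)` around the TSS,
* `b` (gene body): `[+300, TES)`,
* `c` (termination region): `[0, +4000)` from the TES.

The **traveling ratio** is `TR = (d_a + eps) / (d_b + eps)` and the **3'
pausing index** `PI3 = (d_c + eps) / (d_b + eps)`, with `d_*` per-base
densities from `window_density()` and `eps = 0.01` a per-base pseudocount
that keeps ratios finite and positive on sparse data (at `eps = 0` the TR
is exactly scale invariant, which the suite checks to 1e-12). Higher TR
means more polymerase parked at the promoter relative to the body — less
pause release; higher PI3 means accumulation past the TES — slower
termination. The `a`/`b` extents follow the traveling-ratio convention
established in the Pol II pausing literature; the termination window
matches the 4-kb profiling flank. All three are configurable because
different studies draw these windows slightly differently.

Genes whose body window is empty after orientation and clipping (length
≤ 300 bp) are skipped with a message and reported `NA` rather than
silently dropped.

## Confidence tiers

`assign_tiers()` ranks genes by average signal over
`[TSS - 4 kb, TES + 4 kb]` (descending, ties broken by gene id so the
result is order-independent) and cuts at cumulative rank fractions 30%
and 50%: high = ranks `1..ceiling(0.30 N)`, intermediate up to
`ceiling(0.50 N)`, low the rest. The ceiling rule is the one consistent
with all three published partitions this arithmetic is known for
(515 → 155/103/257, 1994 → 599/398/997, 680 → 204/136/340); a floor rule
gives 154 for N = 515 and was rejected. `p * N` is rounded to 6 decimals
before the ceiling because double arithmetic can land an exact integer a
few ulp high (e.g. `0.3 * 680`).

## Comparing conditions

`compare_conditions()` applies the two-sided Mann-Whitney rank-sum test
to two vectors of per-gene TR (or PI3) values — exact for small tie-free
samples, tie-corrected normal approximation otherwise — and reports the
U statistic, p-value, medians and direction. The test is deliberately
distribution-free: TR distributions are heavy-tailed ratios. The suite
cross-checks it against full enumeration of the permutation distribution
at n ≤ 8 and against a Monte-Carlo permutation test at n = 20 + 20.

## Chromatin state and integration

`classify_genes()` scores three histone marks in the standard windows —
H3K4me3 within ±2 kb of the TSS, H3K79me2 in the first 5 kb of the body,
H3K27me3 within ±5 kb of the TSS — by peak overlap (≥ 1 bp of a called
peak; presence/absence, not signal strength). The default rule table is
the standard bivalent-domain definition: bivalent = K4 ∧ K27, active =
(K4 ∨ K79) ∧ ¬K27, silent otherwise. The full 8-row table is replaceable
because the flag-to-label mapping is a modelling choice, not a fact of
the data; swapping tables changes labels only, never the flags.

`filter_de()` thresholds a differential-expression table on absolute fold
change, p and FDR (boundary equality included). Three published-style
cutoff presets are named in `de_presets()` because reported cutoff sets
vary across (and sometimes within) studies; the default is
fold > 1.5, p ≤ 0.05, FDR ≤ 0.1. `annotate_peaks()` assigns each peak one
feature by the precedence promoter > three_prime > exon > intron >
intergenic, anchored at the summit when available, else the midpoint,
with "promoter" meaning anchor within 1 kb of the nearest TSS. The
promoter-first precedence reflects the promoter-centric question the
pipeline answers; it and both distances are parameters. Genes read from
BED6 carry no exon models, so body-overlapping peaks annotate as intron;
supply BED12 to distinguish exon hits.

## The simulator: what it emulates and what it does not

`simulate_reads()` draws each gene's fragment 5' ends from a
four-component mixture: promoter `Normal(TSS + 50, 80)` bp, body
`Uniform[TSS + 300, TES)`, terminal `Normal(TES, 300)` bp, and a uniform
chromosome-wide background; per-gene read counts are
`Poisson(expression)` with `expression = 500` reads by default. Default
weights (0.45 / 0.40 / 0.10 / 0.05) describe an actively transcribed,
moderately paused gene. The depletion condition is
`apply_depletion()`: multiply the promoter weight by 2 and the body
weight by 0.5, renormalize — promoter accumulation plus body depletion at
unchanged expression, the qualitative signature of losing a
pause-release factor. Synthetic genomes (`simulate_genome()`) place 200
genes of 2–10 kb with 12–20 kb gaps, so every gene is isolated by more
than 4 kb and no mark window reaches a neighbour.

Deliberate simplifications, hence limits on what passing tests show about
real data: 5' ends are drawn directly (no fragment-size distribution, no
sequence, no mappability or GC structure); counts are Poisson, not
negative-binomial (no biological overdispersion between replicates);
background is uniform (no input-chromatin structure); marks are emitted
noiselessly inside their windows. The suite's parameter-recovery results
(planted promoter weight vs estimated TR, depletion shift detection)
demonstrate the estimators are correct and sensitive under this model —
not that real libraries are this clean.

## Problem sizes and determinism

Every stochastic function takes a mandatory seed and is reproducible to
the byte; the pipeline driver (`run_pipeline()`) stamps each output with
a hash of its configuration and is idempotent. The validation suite runs
cohorts of 200 genes at 1e5 reads per condition — 50 seeded replicates
for the parameter-recovery checks — sizes at which the Monte-Carlo error
of the checked summaries (median TR ordering, rank correlations ≥ 0.8,
shift p-values) is far from their thresholds while the whole suite stays
interactive.

## Known limitations

* No BAM input: reads enter as BED6 intervals (alignment and duplicate
  marking are upstream concerns).
* Input-chromatin subtraction is not implemented; division by a reference
  track via `normalized_occupancy()` is the supported alternative.
* Peak calling is consumed, not performed; "high-confidence" peak
  selection beyond score-rank tiers is left to the caller.
* The exon/intron distinction depends entirely on the annotation's exon
  models.
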