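---
title: "Detecting large InDels from mate-pair span outliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting large InDels from mate-pair span outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allseq)
```

## The method

An All-seq library combines two fragment populations in a single
sequencing run.  Long genomic fragments (around 6 kb) are circularised
through a Tn5 adapter and re-sheared, so that fragments containing the
circularisation junction carry the adapter between the two ends of the
original long fragment: these are the **mate-pair (MP)** fraction.
Fragments without the junction are ordinary short **shotgun (SG)**
fragments (around 330 bp).  After alignment of the two junction flanks,
the *span* of a mate pair — the outer distance between its two mapped
reads, 1-based and inclusive on both ends — estimates the length of the
original circularised fragment.

On a genome without structural variation, spans concentrate tightly
around the library size.  A deletion between the two flanks inflates
the reference-mapped span by the deleted length; an insertion compresses
it.  The caller therefore:

1. computes spans for all same-chromosome ("intra") pairs, setting
   aside inter-chromosomal pairs as translocation candidates;
2. summarises the span distribution by its quartiles and flags as
   discordant any span below `Q1 - 1.5*IQR` or above `Q3 + 1.5*IQR`
   (the boxplot outlier rule).  For a library with quartiles 5,700 and
   6,300 bp this gives the thresholds 4,800 and 7,200 bp.  Spans equal
   to a threshold are normal: the discordance inequalities are strict;
3. clusters same-class discordant pairs by single linkage and emits a
   call for every cluster with at least `min_support` pairs, with
   size estimate `mean(cluster span) - median(library span)` for
   deletions and the negated difference for insertions;
4. drops calls smaller than `min_size` (default 1,000 bp — the method
   targets *large* InDels only).

The deletion interval is placed between the innermost read edges of the
cluster, `[max(left-read ends) + 1, min(right-read starts) - 1]`,
clipped to a point when the reads overlap.  This is a span-level
method: breakpoints are resolved to roughly a read length plus the
span spread, not to the base pair, which is why downstream validation
by PCR across and inside the candidate interval matters.

## Coordinate conventions

All internal coordinates are 1-based and inclusive, under which a
region written `Chr1:212,499,519-213,348,230` has length
`interval_length()` = 848,712 nt.  Only BED input/output converts to
0-based half-open coordinates.  VCF output uses symbolic `<DEL>`/`<INS>`
alleles with `END` and `SVLEN` (negative for deletions); deletion
`POS` is the base before the deleted interval, and reading recovers
the interval from `END` and `SVLEN` so the round trip is exact.

## Parameters that matter

* `min_mapq` (default 30): mapping-quality floor applied to both
  mates.  The method depends on uniquely mapped flanks; 30 is a
  conventional uniqueness proxy and is configurable.
* `min_support` (default 3 pairs): smallest cluster promoted to a
  call.  At a mate-pair sequence depth of ~1.4x a real large deletion
  is straddled by tens of pairs, while isolated span outliers from the
  distribution tail rarely co-locate three deep; 3 suppresses most
  singleton artifacts without costing sensitivity.
* `cluster_window` (default: the library median span, ~6,000 bp):
  linkage reach when merging discordant pairs.  Two pairs are linked
  when their outer intervals share at least one base *and* both their
  start and end positions agree within the window; single-linkage
  closure then defines clusters.  Pairs supporting the same event
  always satisfy this (their outer intervals all contain the event),
  while unrelated outliers a window apart do not chain.
* `min_size` (default 1,000 bp): reporting floor.  Note the intrinsic
  detection floor is set by the thresholds, not this filter: a
  deletion D is visible only when D plus a typical span clears the
  upper threshold — for the median fragment that means D > 2*IQR
  (~1.2 kb for a 0.6 kb-IQR library), so 1 kb events are marginal
  while >= 10 kb events are recovered essentially always.
* `fixed_thresholds`: the 4,800/7,200 bp pair can be supplied instead
  of refitting, to reproduce a previously fitted configuration; both
  modes are supported because either is defensible for a stable
  library design.
* Comparison `ro` (default 0.5): two calls match when each covers at
  least half of the other (50% reciprocal overlap), the conventional
  SV-matching criterion; the matching rule behind published
  "sample-specific" counts is rarely stated, so it is exposed as a
  parameter.
* Expression thresholds `on = 1.0`, `off = 0.1` RPKM: transcription
  loss/gain is presence/absence, not differential expression.  The
  two-threshold (hysteresis) rule labels a gene LOSS only when it is
  clearly expressed in the reference (>= 1 RPKM) and clearly silent in
  the focal sample (< 0.1 RPKM), which avoids labelling noise-level
  fluctuations around a single cutoff.
* PCR `max_product` (default 3,000 bp): amplifiable ceiling implied by
  short extension protocols; `max_mismatches` defaults to 0 because
  the module predicts validation-design outcomes, not hybridisation
  thermodynamics.

## The simulator, and what it does not model

`sim_config()` defaults emulate the target library: median span
6,000 bp with IQR 600 bp, shotgun fragments 330 +/- 35 bp (about 85%
within +/- 50 bp), 150 bp reads, mate-pair depth 1.43x and shotgun
depth 37.83x.  Two modelling choices deserve emphasis:

* **Span distribution family.** Only the median and IQR of the span
  distribution are constrained by the library description; the family
  is not.  Spans are drawn Normal with sigma = IQR/1.349.  A normal
  tail places ~0.7% of concordant pairs beyond the 1.5*IQR fences,
  which is *heavier* than tightly size-selected real libraries
  (~0.15% observed); simulated precision is therefore, if anything, a
  pessimistic estimate.
* **Depth convention.** Depth is sequence (read-base) depth: the
  number of mate pairs is `mp_depth * genome_length / (2 *
  read_length)`.  At 1.43x and 150 bp reads this yields a physical
  (span) coverage of ~28x, so every >= 10 kb deletion is straddled by
  tens of pairs.

The generator first builds a uniform-random genome
(`make_genome()`), implants non-overlapping variants with an exact
altered-to-reference coordinate map (`apply_variants()`), then draws
fragments on the altered genome and maps read placements back to
reference coordinates (`simulate_reads()`).  Reads that cross a
variant junction or fall in inserted sequence are dropped, as an
aligner would fail or clip them.  Raw-read output represents the MP
junction as fragment-tail + adapter + fragment-head, so
`split_reads()` recovers the two genomic flanks exactly; truth labels
ride in read names.  By default reads are error-free and base
composition is uniform — the method under test consumes spans, not
base accuracy — so passing simulations say nothing about alignment
ambiguity in repeats, chimeric artifacts, or GC-coverage bias in real
data.  Insertions larger than the library span are a structural blind
spot (no pair can straddle them with both reads in flanking sequence):
the simulator demonstrates this ceiling rather than hiding it.

Fragments whose span exceeds the chromosome are resampled (counted);
multi-junction chimeric reads are not simulated, but `split_reads()`
discards and counts them when present.

## Numerical choices and degenerate inputs

* Quartiles use linear interpolation on the sorted sample (R's
  default "type 7"); the estimator matters at small n, so it is
  pinned and the worked threshold example (quartiles 5,700/6,300 ->
  4,800/7,200) is asserted in the tests.
* Percentages reported next to counts (specificity, size bins,
  intra-share) use round-half-up to integers, which reproduces the
  printed 9 / 75 / 11 / 14 / 99 values from their printed counts.
* Size bins are half-open on the right, `[10 kb, 50 kb)` etc., with an
  explicit underflow bin, so bins partition the input.
* Adapter matching is Hamming-distance substring search, no indels
  (Tn5 junctions are fixed-length); best occurrence = fewest
  mismatches, leftmost on ties, forward orientation on
  orientation ties.  The adapter sequence is a required parameter of
  the splitter — there is no universal default in the field, and the
  simulator's Tn5 mosaic-end default is its own synthetic choice.
* Zero-IQR span samples give equal thresholds and no discordant pairs
  rather than an error; fewer than 4 spans is an error.
* Overlapping mates produce a valid (small) span; boundary spans equal
  to a threshold are NORMAL.
* Inter-chromosomal pairs are never promoted to calls; they are
  reported as translocation candidates only.

## Problem sizes used in the checks

The bundled verification suite exercises the caller at desk scale: a
10 Mb single-chromosome genome with 20 implanted deletions of
10-200 kb at default depths, five seeds, which completes in seconds
and recovers essentially all implanted events (mean precision and
recall >= 0.9 at 50% reciprocal overlap); smaller 1-2 Mb fixtures
cover the split stage, the detection floor at 1/10/100 kb, the
sub-1 kb reporting filter, and the insertion ceiling.  These sizes
were chosen as the smallest at which cluster statistics are stable;
conclusions about much deeper libraries or repeat-rich genomes require
real alignments.

## Worked example

```{r example}
cfg <- sim_config(genome_length = 2e6, seed = 7)
lens <- c(chr1 = 2e6)
vars <- random_variants(lens, n_del = 3, del_size_range = c(20e3, 80e3),
                        seed = 8)
sim <- simulate_reads(cfg, truth = apply_variants(lens, vars),
                      output = "pairs")
calls <- call_indels(sim$pairs, caller_config(), sample_id = "simcell")
calls
coef(attr(calls, "span_stats"))
evaluate_calls(calls, vars, ro = 0.5)
```

## Known limitations

* Span-only evidence: orientation is recorded but unused, so
  inversions and duplications are out of scope, as is SNP calling
  from the shotgun fraction.
* Breakpoints are approximate (no split-read refinement).
* Insertion sizes are bounded by the library span, and insertion
  calls carry point intervals with window-scale uncertainty.
* The multi-sample comparison assumes call sets on the same reference
  with comparable depth; it labels, it does not genotype.
* TAD fusion flagging consumes externally called TAD intervals; it
  does not compute domains from contact maps.
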