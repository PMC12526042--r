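---
title: "G-quadruplex calling and proximal enhancer-promoter pair analysis"
author: "gqpep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-quadruplex calling and proximal enhancer-promoter pair analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqpep)
```

## The problem

G-quadruplexes (GQs) are four-stranded structures formed by guanine-rich
DNA. The canonical encoding is four G-runs of 3-5 guanines separated by
three loops of 1-7 arbitrary bases, so the shortest canonical motif is
4·3 + 3·1 = 15 bp and the longest 4·5 + 3·7 = 41 bp. GQs form transiently
and are strongly enriched in regulatory elements; genome-wide experimental
maps produced by different assays overlap poorly, which motivates
aggregated, confidence-leveled call sets (levels 1-6, the number of
independent experiments supporting a call) and model-based genome-wide
prediction. This package implements the analysis layer around such call
sets: building training windows for a sequence classifier, calling GQs with
a pluggable scorer, and asking where the calls sit relative to promoters,
proximal enhancers (pELS) and single-cell ATAC-RNA feature linkages.

All coordinates are carried as `GRanges` (1-based closed, the Bioconductor
convention); every file format and exported coordinate table is BED-style
0-based half-open, converted at the boundary by `gintervals()` /
`gr_to_bed_df()`. Using the platform containers rather than a bespoke
0-based structure keeps the interval algebra on `IRanges`, which is
exhaustively tested upstream; the package's own per-base-mask oracle tests
guard the wrapper semantics (1-bp overlap, half-open adjacency, gap
bridging).

## Training-window construction

Positive signal is the union of bases covered by calls at confidence level
`level_min` (default 4) on per-chromosome logical tracks. Chromosomes are
tiled into non-overlapping `window_size` = 512-bp windows; a window is
positive iff any of its bases is positive. Trailing partial windows are
dropped: tiling is defined in fixed units and a partial tile has no
defined treatment. Negatives are sampled uniformly without replacement at
`neg_ratio` = 2 per positive from the same tiling, once globally; the
dataset is then split into `k_folds` = 5 folds by a seeded shuffle
stratified by label, so each of the five models trains on 80% of positives
and negatives alike. Fold randomization is a design choice here
(stratified uniform); any scheme that keeps folds disjoint and
class-balanced would serve. Ensemble prediction averages all `k` models for
windows outside the dataset and the `k - 1` non-held-out models for dataset
windows (`ensemble_score()`).

## GQ calling

`find_canonical_motifs()` scans both strands for the canonical grammar with
a fully specified, deterministic policy: positions are visited left to
right; at the first position admitting a match the *shortest* match
starting there is taken, ties broken by minimal run lengths then minimal
loop lengths, left to right; scanning resumes after the match end, so
matches are non-overlapping per strand. The grammar names the motif but not
an extraction policy, so the policy is fixed and documented here; tests
compare the scanner against an independent anchored-regex enumeration on
random corpora. `N` is permitted in loops and never counts toward a G-run.
Loops may contain guanines (they are unconstrained positions), which
matters for long G-tracts: 12 consecutive guanines contain no match, while
15 do.

`call_genome()` places 512-bp scoring windows at starts 0, `stride`,
2·`stride`, ... while a full window fits, and keeps only the central 128 bp
of windows scoring at or above `threshold` = 0.25, so every retained base
has at least 192 bp of context on each side. No padding is used at
chromosome ends - a window without full context is simply not placed. The
default `stride` = 192 leaves 64-bp gaps between consecutive 128-bp
centers; `stride = 128` gives gap-free center coverage. Both are exposed
because the two goals - a 192-bp step and complete coverage by 128-bp
centers - cannot hold simultaneously; the package treats the stride as an
explicit parameter rather than resolving the tension silently. Retained
centers are merged (`merge_gap` = 0, the conservative choice: only
touching or overlapping centers join), motif-supported sub-intervals are
kept where canonical motifs are present (with the motif's strand), and
calls narrower than `min_len` are dropped. `min_len` defaults to 15, the
canonical minimum; it is configurable because shorter cutoffs (down to 6)
are sometimes used for genome scans.

The default scorer is the motif-coverage scorer: central-128-bp bases
covered by any canonical motif, divided by 15 and capped at 1. It is a
transparent stand-in honoring the pluggable contract (512-bp sequence in,
[0, 1] out); a learned model can be substituted as an R function or via an
imported per-window score track (`score_track`). Inside `call_genome()` the
default score is computed from one whole-chromosome motif scan rather than
per-window rescanning; the two differ only for motifs truncated at window
edges, which cannot reach the 192-bp-buffered center.

## Promoters, regions, pEP pairs

Promoters cover 1000 bp upstream and 200 bp downstream of the strand-aware
TSS, mirrored on the minus strand (a minus-strand transcript with 0-based
TSS t has promoter [t−199, t+1001) in 0-based half-open coordinates) and
clipped at chromosome bounds. Region classification assigns each interval
the highest-precedence label it overlaps: promoter > 5'UTR > 3'UTR > exon >
intron > intergenic. The precedence is a declared convention (promoters
first, matching how promoter-dominated the method comparisons are); a GQ
overlapping several genes is classified once, so fractions sum to 1. UTR
labels require UTR tracks in the annotation; otherwise those bases fall
through to exon.

A pEP pair is one transcript plus one pELS overlapping its promoter by at
least 1 bp; all transcript × pELS combinations are kept, so one enhancer
can join many pairs. `flag_gq()` marks each side by ≥ 1 bp GQ overlap,
optionally extending both sides by a flank; the flank defaults to 0 and a
±100 bp mode mirrors DNase-site-sized windows used with curated enhancer
databases. Distal elements (dELS) are deliberately out of scope.

`enrichment()` compares the observed share of doubly-flagged pairs with
the independence product of the two flag frequencies. The default computes
frequencies over the pair universe (the most direct reading of multiplying
per-side frequencies); an element-level alternative (each distinct
promoter/enhancer counted once) is available via `expected = "element"`
since the two differ when enhancers are shared unevenly. The Fisher test is
the two-sided conditional exact test on the promoter-flag × enhancer-flag
pair table, delegated to `stats::fisher.test`; the reported odds ratio is
the sample ad/bc, not the conditional MLE. The permutation null re-places
each query interval uniformly within its own chromosome, preserving widths,
with no exclusion zones - the simplest null compatible with the question -
and uses the add-one p-value estimator. `top_fraction()` takes
k = round(frac·n) (banker's rounding) elements by score with (chrom, start)
tie-breaks, so the selection is deterministic for any input order.

## Multiome linkage and state comparison

Linkage records (peak interval, gene, signed correlation, sample) are
filtered at |r| strictly greater than the threshold ("over 0.2"
semantics; the boundary record is dropped, and the threshold is a
parameter). An element is "open" iff a retained peak overlaps it; a pair is
open iff both sides are. A pair's link requires the record's gene to match
the pair's gene *and* its peak to overlap the pair's promoter or enhancer -
gene identity disambiguates multi-gene loci. The positive-correlation share
is per-link by default; per-pair and per-gene weightings are exposed
(`by =`) because the aggregation unit is a genuine analysis choice.

A discordant enhancer is a pELS, overlapped by retained peaks, linked with
opposite signs to two distinct genes whose promoter regions either both
overlap the pELS or sandwich it. When several genes qualify on one side the
nearest promoter wins. This is the geometry of a candidate tissue-specific
switch: accessibility up with one neighbour's expression, down with the
other's.

State comparison builds the pair universe per cCRE track against a shared
GQ set and annotation (predictions are state-agnostic; only the cCRE
tracks differ) and partitions GQ-bearing promoters (by transcript id),
enhancers (by exact coordinates) and pairs (by both) between states.
Exact-coordinate identity is the declared convention; elements shifted by a
few bases count as distinct.

## The synthetic-data generator

`gen_genome()` writes i.i.d. background bases at a configurable GC content
(default 0.41, human-like) and plants non-overlapping canonical motif
instances - runs 3-5, loops 1-7 of non-G bases - on uniformly chosen
strands, with 2-bp A/T buffers so neighbouring background guanines never
extend a planted instance. A minus-strand motif appears as C-runs on the
forward strand, exercising strand handling. `gen_annotation()` lays genes
in evenly spaced slots (1-3 transcripts each, random strand, two exons), a
PLS over each TSS, optionally a pELS straddling the upstream promoter edge
(~100 bp inside the −1000/+200 window, the rest outside - guaranteeing
both a pEP pair and promoter-free enhancer territory), and a dELS well away
from any TSS. Divergent head-to-head gene pairs with one shared pELS inside
both promoter windows provide the discordant-enhancer geometry.
`gen_gq_calls()` emits each truth interval at level k with probability
`levels_model[k]` (default mix shaped like aggregated databases: most calls
weakly supported, roughly a third at levels 4-6, 7% at level 6), with
optional boundary jitter and false positives. `gen_linkages()` gives each
open gene a ~500-bp peak overlapping its promoter and pELS with a
truncated-normal correlation, positive in 90% of records by default, and
plants discordant peaks with +0.67/−0.61 correlations to the divergent pair
- the worked switch geometry.

For null calibration of the enrichment ratio, `null_gq_model()` /
`gen_null_gq()` plant fixed-width GQs independently in each promoter's
largest pELS-free zone and each pELS's largest promoter-free zone, making
the two pair flags independent by construction.

What the generator does *not* emulate: repeat structure and GC
heterogeneity of real genomes, realistic cCRE size/density distributions,
multi-sample cell-type structure (one sample per table; multi-sample
analyses concatenate tables with distinct tags), read-level data, or
expression counts. Passing tests therefore demonstrate the correctness of
the interval logic, the scanner, the estimators and the detection
procedures under controlled conditions - not the biological accuracy of
any learned scorer on real genomes.

## Problem sizes and numerical choices

The standing test conditions are a 2-Mb genome (two 1-Mb chromosomes) with
300 planted motifs and 50 genes; scanner-oracle corpora use 10,000 random
strings of length 15-41 (uniform, G-rich and mutated-motif thirds); null
calibration uses 200 seeds for the enrichment-ratio mean and 100 replicates
of a 999-permutation test for p-value uniformity (150 query × 300 subject
intervals on a 100-kb chromosome, sized so the permutation statistic takes
enough distinct values for a meaningful uniformity check). Determinism:
every stochastic routine takes an explicit seed and fixed seeds give
byte-identical outputs; inference (`call_genome`) has no randomness.
Degenerate inputs are errors, not silent results: empty query sets for
overlap fractions, empty truth for recall, empty pair universes, promoters
clipped to nothing, calls beyond chromosome ends.

## Known limitations

* The default motif-coverage scorer is deliberately simple; it recovers
  planted canonical motifs perfectly but is not a model of non-canonical
  GQ formation. Learned scorers plug in via the scorer contract or score
  tracks.
* Fisher p-values on very large pair universes are effectively 0; the
  enrichment ratio, not the p-value, is the interpretable quantity there.
* The permutation null ignores accessibility/GC covariates; folds keep
  whole windows but adjacent windows can still be correlated by proximity.
* UTR classification depends entirely on provided UTR tracks.
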