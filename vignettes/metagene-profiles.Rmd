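---
title: "Metagene profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagene profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the model behind each stage, the parameters that matter, the numerical
conventions, what the synthetic data generator does and does not emulate,
and the design decisions taken where more than one reasonable choice
existed.

## The pipeline model

A metagene analysis aggregates ChIP-Seq read depth over a *region group* —
a set of genomic windows resized to one common width and anchored on their
centers — into a single curve per group and experiment. The stages, in
order:

1. **Regions.** BED / narrowPeak / broadPeak input; every region is
   replaced by `[center − flank, center + flank)` where the center is the
   floor of the midpoint in 0-based coordinates. Windows that would cross a
   chromosome boundary are *dropped*, not clamped: a clamped window would
   break the rectangular coverage matrix that all later stages assume.
   Internally regions live in `GRanges` (1-based, closed); conversion to
   and from BED's 0-based half-open convention happens only at file I/O, so
   a read/write cycle round-trips coordinates exactly.
2. **Coverage.** Depth at a base is the number of selected reads (mapped,
   primary, non-supplementary; duplicates kept by default) whose aligned
   span covers it. Spans include CIGAR deletions and exclude reference
   skips. Per-region vectors are kept run-length encoded; storage scales
   with signal complexity, not window width. Minus-strand regions are
   reversed so every row reads 5'→3'.
3. **Background scaling (NCIS-style, fixed bins).** The control measures
   noise only, the ChIP measures signal + noise, so the control must be
   scaled to the *noise* component before subtraction. Reads are binned by
   their 5' position into `bin_size` genome bins (default 1000 bp; floor
   100 bp, below which bins are too sparse to rank). Bins are sorted by
   total count and the cumulative ratio r(t) = Σchip/Σcontrol over bins
   with total ≤ t is scanned over increasing thresholds: while only
   background bins accumulate, r(t) drifts downward; signal bins entering
   the sum make it rise. The estimate is taken at the first non-decrease,
   subject to covering at least 75% of non-empty bins (the
   `background_quantile`), falling back to the all-bin ratio when r
   decreases throughout. The 75% floor and first-non-decrease stop are the
   fixed-bin variant of the published NCIS procedure; both are exposed as
   arguments.
4. **Subtraction and units.** `max(0, chip − r·control)` per base, then
   reads per million aligned (RPM) using the pooled ChIP library size.
   Replicates are pooled by summing raw counts *before* any scaling —
   pooled replicates behave like one deeper library, and the noise ratio is
   defined on raw counts. Experiments without a control skip subtraction
   with a warning.
5. **Binning and aggregation.** Positions are averaged in `bin_size`-wide
   bins (default 10 bp) to damp extreme single-base values before
   resampling; a trailing partial bin is dropped with a warning. The group
   curve is the column-wise mean (default) or median across regions.
6. **Bootstrap ribbon.** Regions — the independent sampling units — are
   resampled with replacement B = 1000 times; positions within a region
   stay paired. The ribbon is the pointwise percentile interval holding the
   central `level`% (default 95) of the resampled estimator. Percentile
   intervals were chosen over SE-based ones because the ribbon is defined
   as the span of the sampled values; no BCa or studentized variants.
7. **Permutation test.** For two groups, regions are pooled and reshuffled
   *without replacement* into pseudo-groups of the original sizes N times
   (default 1000); the dissimilarity between the recomputed curves is
   compared with the observed one. `p = (n_extreme + 1)/(N + 1)` with ties
   counted as extreme: the add-one correction is standard for Monte-Carlo
   tests, keeps p > 0, and the ≥ convention is conservative. Similarity
   metrics are flipped to `1 − value` by an explicit adapter.

## Pseudometrics and the plateau rule

Six pseudometrics compare equal-length non-negative curves; each targets
one profile feature (total amplitude, peak position, peak height,
pointwise overlap, shape after amplitude normalization, rank agreement).
Every metric carries editable validity thresholds (minimum peak height 1,
minimum area 1, non-degenerate variance) and returns an explicit
*undefined* result with a reason instead of propagating NaN or extreme
ratios from empty profiles. Tied maxima resolve to the median of the tied
positions, which is stable under symmetric plateaus.

The recruitment classification compares the moderate- and high-activity
profiles of one factor: RATIO_INTERSECT ≥ 0.85 means the two curves nearly
coincide — occupancy has saturated before maximal activity (*threshold*
effect); below the cutoff occupancy still rises with activity (*gradient*
effect). The 0.85 cutoff is the rule's decision constant and an argument of
`classify_effect()`.

## Activity stratification

`stratify_by_score()` splits a scored region group into `none` (score
exactly 0) plus tertiles of the nonzero scores (`low`, `moderate`,
`high`). Tertiles of the nonzero scores are the simplest four-way scheme
consistent with an activity measure in which a large fraction of regions
show no signal at all; the quantile edges are an argument for users whose
activity measure calls for different cutpoints. Ties are broken by input
order so group sizes differ by at most one and the split is deterministic.

## The synthetic data generator

`simulate_experiment()` emulates the structure the pipeline is built for:

* ChIP reads = uniform Poisson background at rate `control_scale ×
  background_rate` per bp, plus per-region `Poisson(amplitude)` peak reads
  whose positions are Gaussian around the region center (SD `sigma`,
  truncated to the region);
* control reads = uniform Poisson background at `background_rate` — a
  matched library with no peak;
* reads are single-end, error-free and uniquely mapped, written as
  coordinate-sorted, indexed BAM; all randomness flows from one seed and
  output is byte-identical per seed.

Defaults: `amplitudes = (none 0, low 100, moderate 250, high 500)` expected
peak reads per region, `sigma = 100` bp, `background_rate = 0.8` reads/bp,
`control_scale = 2`, `read_length = 50` bp. The miniature genome (hundreds
of kb) stands in for the regions-of-interest fraction of a real genome, so
the per-bp rate corresponds to pooled, deeply sequenced libraries rather
than genome-wide shallow coverage. That depth matters for a structural
reason: clamped subtraction `max(0, chip − r·control)` has a positive
expected residual of roughly `sd(chip − r·control)/√(2π)` per base, so the
residual *fraction* of the background scales as `√((1 + c)/(2π·depth))`.
At the default ChIP background depth (≈ 80×) the expected residual is
under 10% of the uncorrected background; at 1× depth it would be the
majority of it. Consequently, passing tests demonstrate correct behaviour
for well-powered (deep or pooled) libraries; on shallow single libraries
the clamped residual is a known, documented bias of this (standard)
subtraction rule, not a defect of the estimator of r.

The generator does not emulate GC or chromatin-accessibility bias,
mappability, read errors, duplicated fragments, or fragment-length
asymmetry between strands — tests passing on synthetic data say nothing
about robustness to those artefacts.

## Numerical conventions

* Region centers: floor of the 0-based midpoint (deterministic integer
  arithmetic).
* Median over an even number of regions: midpoint average
  (`stats::median`).
* Ribbon percentiles: `stats::quantile` type 7 (the R default).
* Degenerate cases: single-region matrices yield a zero-width ribbon with
  a warning; an all-zero profile pair makes intersection metrics undefined
  rather than 0/0; a metric undefined on a permuted split drops that round
  (with a warning and a reduced N) rather than poisoning the p-value.
* One seed governs an analysis; bootstrap and permutation draws consume it
  in a fixed order, so a configuration plus seed reproduces every output
  file byte-for-byte.

## Problem sizes used by the test suite

The suite exercises desk-scale versions of the study conditions: region
groups of 8–200 regions, windows of 1–2 kb, libraries of 10³–10⁶ reads,
500-replicate simulation studies for ribbon calibration (B reduced to 200)
and permutation size (N = 200). These sizes were chosen so the full
statistical checks — bootstrap coverage between 90 and 98%, type-I error
within [0.03, 0.07] — run in minutes while keeping Monte-Carlo error well
inside the asserted bands.

## Known limitations

* The noise ratio uses the fixed-bin NCIS variant only; no
  increasing-bin-size schedule, no SES or spike-in scaling.
* Paired-end mates contribute their spans independently; no fragment
  reconstruction (an optional 5'-extension approximates fragments).
* No multiple-testing correction across many factor comparisons is
  applied; downstream Benjamini–Hochberg over the permutation p-values is
  recommended.
* The interactive heatmap of the historical GUI is replaced by a static
  matrix export plus image (`export_heatmap_matrix()`).
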