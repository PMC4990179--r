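# metaprofiler

Metagene profiles of ChIP-Seq enrichment with background correction,
bootstrap confidence ribbons, and quantitative profile comparison.

## The problem

A ChIP-Seq experiment measures where a protein sits on the genome, but a
single locus is noisy: the informative signal is the *aggregate* occupancy
pattern over hundreds or thousands of comparable regions — promoters,
enhancers, peaks of another factor. The standard summary is the metagene
(aggregation) plot: the average read coverage across a group of aligned
regions, plotted against position relative to a common anchor.

Raw metagene curves are hard to compare across samples, because ChIP signal
is a mixture of true enrichment and background noise, and libraries differ
in depth. `metaprofiler` builds comparable curves and then makes the
comparison quantitative:

1. **Per-region coverage** is extracted from coordinate-sorted, indexed BAM
   files over uniform-width windows, stored run-length encoded, and
   oriented 5'→3' so strand-asymmetric patterns align.
2. **Background correction.** The control cannot simply be scaled by the
   library-size ratio: the ChIP library is signal + noise while the control
   is noise only. Following the NCIS idea, the noise scaling *r* is
   estimated from low-signal genomic bins — ranking bins by combined count
   `t_i = chip_i + control_i` and tracking the cumulative ratio
   `r(t) = Σ chip / Σ control` over bins with `t_i ≤ t` until it stops
   decreasing (with at least 75% of non-empty bins included). The corrected
   coverage is `max(0, chip − r · control)` per base.
3. **Normalization** to reads per million aligned (RPM) makes curves
   comparable across libraries; replicates are pooled by summing raw counts
   first.
4. **Uncertainty.** Positions are binned (mean per bin), then the
   per-group mean (or median) curve gets a percentile bootstrap ribbon:
   regions are resampled with replacement B = 1000 times and the ribbon
   spans the central 95% of the resampled estimator at each position.
5. **Comparison.** Two group profiles are compared by a permutation test
   (pool the regions, reshuffle group labels, recompute the
   dissimilarity; `p = (n_extreme + 1)/(N + 1)`) and by six
   profile-similarity pseudometrics: RATIO_AREA, DIFF_POS_MAX,
   RATIO_MAX_MAX, RATIO_INTERSECT (`Σ min(p1,p2) / Σ max(p1,p2)`),
   RATIO_NORMALIZED_INTERSECT, and SPEARMAN_CORRELATION. The
   intersection-ratio rule classifies a factor's response to rising
   regional activity: RATIO_INTERSECT ≥ 0.85 between the moderate- and
   high-activity profiles means occupancy has plateaued (a *threshold*
   effect), anything lower means occupancy still tracks activity (a
   *gradient* effect).

A seeded synthetic-data module generates BAM/BED/design fixtures with known
enrichment structure (Gaussian peak over uniform Poisson background, plus a
matched peak-free control), so the whole pipeline is testable end to end
without external data.

## Worked example

Simulate a two-class experiment (moderate vs high activity, peak
amplitudes 250 and 500 expected reads per region, ChIP background twice the
control) and run the pipeline:

```r
library(metaprofiler)

sim <- simulate_regions(n = 120, width = 2000, n_chrom = 2,
                        chrom_length = 3e5, seed = 1)
regions <- sim$regions
regions$group <- rep_len(c("moderate", "high"), length(regions))
ex <- simulate_experiment(
  regions, simulation_truth(amplitudes = c(moderate = 250, high = 500)),
  sim$chrom_sizes, dir = tempdir(), seed = 2)

# ... write the per-group BEDs, chrom.sizes and a 2-line design sheet, then:
res <- run_metagene(default_config(
  regions = c(moderate = "moderate.bed", high = "high.bed"),
  design = "design.tsv", chrom_sizes = "chrom.sizes",
  flank = 1000, bin_size = 10, B = 1000, seed = 42))
res
#> MetageneAnalysis: 2 profile(s), 1 noise ratio(s)
#>   tf: r_hat = 1.998347
head(res$table, 3)
#>               experiment    group position    value   ci_low  ci_high
#> tf.moderate.1         tf moderate     -995 6.563537 4.422326 8.603976
#> tf.moderate.2         tf moderate     -985 7.361745 4.868088 9.919125
#> tf.moderate.3         tf moderate     -975 6.600177 4.443175 8.967646
```

The estimated noise ratio `r_hat = 1.998` recovers the simulated truth
(ChIP background exactly twice the control). The table rows are bin centers
in bp relative to the region center with the RPM estimate and its 95%
bootstrap ribbon; `plot_metagene(res)` draws the curves and ribbons.

Is the high-activity profile a scaled-up version of the moderate one, or
the same plateau?

```r
classify_effect(res$profiles[["tf.moderate"]]$curve,
                res$profiles[["tf.high"]]$curve)
#> EffectClass: gradient (RATIO_INTERSECT = 0.5983433, cutoff = 0.85)

permutation_test(res$matrices[["tf.moderate"]], res$matrices[["tf.high"]],
                 N = 1000, seed = 43)
#> PermutationResult: mean_abs_diff observed = 7.060675, p = 0.000999
#>   (0 of 1000 rounds >= observed)
```

The doubled amplitude shows up as a gradient-type response (intersection
ratio 0.60, well below the 0.85 plateau cutoff) and the permutation test
rejects profile equality at the smallest attainable p-value, 1/(N+1).

A command-line wrapper lives at `inst/cli/metaprofiler.R`
(`run` / `simulate` / `compare` subcommands); an optional full-scale script
for user-supplied ENCODE GM12878 data is `inst/scripts/reproduce_encode.R`.

## See also

The methods vignette (`vignettes/metagene-profiles.Rmd`) documents the
model, the generative assumptions behind the synthetic data, numerical
conventions, and known limitations.
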