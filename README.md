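# paleodiv

Speciation-scale phenotypic divergence statistics for fossil time series
and extant ecotype pairs.

## The problem

A finely resolved stratigraphic sequence of fossil stickleback records a
lineage that colonized a lake basin and then gradually evolved reduction of
armour, swimming and feeding traits over roughly 16 000 years.  Did that
gradual change amount to the beginnings of speciation?  One way to ask is
to compare the lineage's multivariate divergence against a modern
yardstick: the benthic–limnetic "species pairs" of threespine stickleback,
reproductively isolated ecotype pairs that coexist in a handful of lakes.
`paleodiv` implements that inference pipeline for specimen-level trait
tables, plus a synthetic-data generator that emulates the study design so
every stage can be validated against known truth.

## What it computes

For a registry of 16 traits (9 size-corrected lengths, 6 meristic counts,
and standard length `stl`):

- **Armour association screen.**  In samples where high- and low-armoured
  forms co-occur, a 2×2 table of (full pelvis, pelvic score = 3) ×
  (three dorsal spines) is tested with Fisher's exact test.  Random
  association is what interbreeding would produce; perfect association
  indicates reproductive isolation.  Frequencies of the two mixed
  phenotypes are also reported.
- **Preprocessing.**  Values beyond 3.5 pooled standard deviations from
  the dataset-level trait mean are masked to `NA` (single pass).
  Continuous traits are size-corrected with a mixed-model regression on
  standard length (common slope *b*, group random intercepts):
  `corrected = observed − b·(stl − L̄)`, keeping values in mm.  Fossil and
  extant data are corrected separately.
- **Univariate divergence.**  Per trait, the Wilcoxon rank-sum *U* between
  the first and last samples, a two-sided p (normal approximation with
  continuity and tie correction; exact for small untied samples), and the
  common-language effect size `CLES = U / (n_first · n_last)` — the
  proportion of cross-sample pairs in which the later specimen has the
  larger value.  Significance uses the Bonferroni family level
  α = 0.05/16 ≈ 0.003.
- **Multivariate divergence.**  The Euclidean distance
  `d = ||x̄_last − x̄_first||` between trait-mean vectors, with a bootstrap
  distribution (99 within-group resamples) and a permutation test of
  sample identity (99 shuffles, add-one p, floor 0.01).
- **Comparison and timing.**  Welch *t*-tests between the fossil and
  species-pair bootstrap distributions; the divergence trajectory
  `d(first, k)` through time; and the first sample at which the fossil
  mean ± s.d. interval reaches each reference divergence, in years and in
  generations (2 yr/generation).
- **Correlated trait evolution.**  Pearson correlations among the 16
  trait-mean time vectors, summarized by the off-diagonal mean/s.d./median.

## Worked example

```r
library(paleodiv)

sim       <- simulate_fossil_series(seed = 42)   # 18 samples over 16 363 yr
screen    <- detect_outliers(sim$table)          # 3.5 pooled-s.d. screen
masked    <- apply_outlier_mask(sim$table, screen)
model     <- fit_size_correction(masked)         # trait ~ stl + (1 | sample)
corrected <- size_correct(masked, model)
fit       <- divergence(corrected, "K01", "K18", seed = 42)
fit
#> Multivariate divergence between K01 and K18 (16 traits)
#>   d = 18.41  (bootstrap mean 18.36, s.d. 0.582, B = 99)
#>   permutation p = 0.01 (P = 99)
#>   10/16 traits significant at family alpha = 0.003125
sim$truth$true_d
#> [1] 19.68
```

The fitted `d` of 18.41 is the distance, in mm-scale mixed units, between
the first and last sample mean vectors; it sits close to the generator's
true divergence (19.68), the permutation p of 0.01 is the smallest value
attainable with 99 shuffles (no permuted relabelling reached the observed
`d`), and 10 of the 16 traits individually pass the family-corrected
rank-sum test.  `summary(fit)` prints the full per-trait table and
`plot(fit)` shows the bootstrap and permutation distributions.

The armour screen on a simulated mixed sample (7 high-armoured immigrants
among 63 residents, no hybridization):

```r
ct <- dichotomize_armour(
  simulate_armour_sample(armour_scenario_params(63, 7, 0), seed = 1))
ct
#> Armour contingency table (n = 70)
#>          spines
#> pelvis    three fewer
#>   full        7     0
#>   reduced     0    63
fisher_exact_2x2(ct)$p_two_sided
#> [1] 8.341851e-10
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages — simulation,
preprocessing, association, divergence, Welch comparisons, overlap timing
and trait correlations — and writes per-stage artifacts plus a manifest
when `out_dir` is set.

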