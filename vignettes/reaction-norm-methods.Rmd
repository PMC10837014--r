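---
title: "Methods: reaction norms, environment subsetting, and genomic prediction of plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction norms, environment subsetting, and genomic prediction of plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactnorm)
```

## The model

`reactnorm` analyses phenotypic plasticity in multi-environment trials and
common garden experiments through the Finlay–Wilkinson joint regression

$$Y_{ij} = \mu_i + \beta_i I_j + \delta_{ij},$$

where $Y_{ij}$ is the line mean of genotype $i$ in environment $j$, $I_j$ is
the *environmental mean* (the average of all lines in environment $j$, minus
the grand mean so that $\mu_i$ is an intercept), $\mu_i$ is the genotypic
value at the average environment, $\beta_i$ is the plasticity (slope of the
reaction norm), and $\delta_{ij}$ is the deviation from regression. The core
assumption is a *linear* reaction norm over the studied environmental
gradient; everything downstream (consistency scans, prediction, the
environmental-index surrogate) is conditional on it.

Two conventions matter and are fixed throughout:

* The grand mean is the **unweighted mean of the environmental means**. With
  complete data this equals the mean of all line means; with mild imbalance
  from missing genotypes it keeps $\sum_j I_j = 0$ on the environment scale.
* Each genotype is regressed only on its non-missing environments; genotypes
  with fewer than three usable environments are dropped with a warning, never
  imputed.

### Two environments

With exactly two environments the regression is saturated, so
`two_env_parameters()` takes the intercept as the average of the two line
means and the slope as the difference divided by $I_2 - I_1$, with the pair
ordered by ascending environmental mean. Dividing by $\Delta I$ puts these
slopes on the same scale as ordinary least-squares slopes; because it is a
fixed positive rescaling, every Pearson correlation involving them is
identical to the correlation of the raw differences, so no correlation-based
result depends on this choice.

### What a subset's intercept means

When reaction norms are re-estimated inside a subset of environments, the
environmental means are recomputed *within the subset* and re-centered
there. A useful exact identity follows for data generated by the linear
model: the subset intercept of genotype $i$ equals
$\mu_i + \beta_i \bar c$, where $\bar c$ is the subset's average position on
the whole-set index scale. Subset intercepts are genotypic values *at the
subset's average environment*, not at the whole-set average. Consequently,
even noise-free data give subset-vs-whole intercept correlations slightly
below 1 whenever $\bar c \neq 0$ (slopes, by contrast, are exactly
recovered). The test suite asserts both facts — slope consistency exactly 1
and the $\mu + \beta\bar c$ identity to machine precision — rather than a
perfect intercept correlation that the estimator cannot produce. This is
also why, on real data, the intercept correlation of an extreme
two-environment pair can fall below its slope correlation.

## Consistency across environment subsets

`consistency_scan()` enumerates all subsets of size $k_\min$–$k_\max$
(`enumerate_env_subsets()`, lexicographic order; 501 subsets for nine
environments and $k = 2..8$), re-estimates parameters per subset, and
reports Pearson correlations against the whole-set estimates. The subset's
`env_mean_range` is measured on the *whole-set* index scale (max minus min
of the member environments' whole-set $I_j$), so ranges are comparable
across subsets; `range_fraction` divides by the whole-set range. Estimation
failures inside a subset (e.g. a pair with identical environmental means)
are recorded per subset with an `NA` correlation and a note instead of
aborting the scan.

Two summary curves are provided:

* `fit_cube_root()` fits $y = a + b\,x^{-1/3} + e$ by ordinary least
  squares on the transformed regressor — a convenient two-parameter curve
  for how fast consistency rises with range.
* `fit_range_splines()` fits one smoothing spline per environment sample
  size with the smoothing parameter chosen by generalized cross-validation
  (`stats::smooth.spline`). Groups with fewer than four points fall back to
  a straight line (noted), groups with fewer than two are skipped with a
  warning.

## Ridge-regression BLUP with REML

Genomic prediction of $\mu$ and $\beta$ uses the standard whole-genome
shrinkage model $y = 1m + Zu + e$ with $u \sim N(0, \sigma^2_u I_p)$ and
$e \sim N(0, \sigma^2_e I_n)$, written from scratch in `fit_ridge_blup()`:

* The variance ratio $\lambda = \sigma^2_e/\sigma^2_u$ is estimated by
  restricted maximum likelihood. The restricted log-likelihood is profiled
  over $\sigma^2_u$ on a one-time eigendecomposition of the marker kernel
  $ZZ^\top$ projected off the intercept, so each candidate $\lambda$ costs
  $O(n)$.
* The optimum is located by a 25-point grid on
  $\log_{10}\lambda \in [-6, 6]$ followed by golden-section refinement
  between the best grid point's neighbours; exact ties resolve toward the
  larger $\lambda$ (more shrinkage). The bounded search guarantees
  termination; a degenerate (e.g. constant-$y$) likelihood lands on the
  upper bound, giving zero effects and the sample mean, which is the
  sensible limit.
* Effects at the optimum are the ridge/BLUP solution
  $u = Z^\top (ZZ^\top + \lambda I)^{-1}(y - 1\hat m)$ with $\hat m$ the
  generalized-least-squares mean. Missing marker codes are imputed by the
  marker's mean code beforehand — deterministic and adequate for inbred
  panels.

A note on identifiability: $\lambda$ is well resolved when the error
variance is comparable to the *total* marker variance (e.g. per-marker
$\sigma^2_u = \sigma^2_g/p$ with $\sigma^2_g \approx \sigma^2_e$, i.e.
$\lambda \approx p$). If instead the per-marker variance equals the error
variance, every kernel eigenvalue dwarfs $\lambda$ and the restricted
likelihood is nearly flat over orders of magnitude — no estimator can
recover such a ratio to a factor of two, and the recovery tests use the
identifiable parametrization.

### Cross-validation

`cv_genomic_prediction()` implements two scenarios: `"within"` trains and
scores on parameters estimated in the same environment subset; `"whole"`
trains on subset-estimated parameters but scores held-out predictions
against whole-set estimates, asking whether a cheap subset can stand in for
the full series. Folds (default 10) are contiguous blocks of a seeded
shuffle; the seed is stored in the result for exact reproducibility.

Accuracy is the **average of per-fold Pearson correlations**. A single
correlation pooled across folds is biased under weak signal: strong REML
shrinkage collapses predictions toward each fold's training mean, and a
fold's training mean anti-correlates with its held-out mean, which we
measured at roughly $-0.28$ mean "accuracy" for pure-noise phenotypes with
10 folds of 64 lines. Per-fold averaging keeps the no-signal expectation at
zero (measured $|\text{mean}| \approx 0.02$ over 50 permutations) at a
modest variance cost.

## Environmental indices from weather

`daily_gdd()` computes growing degree days with base 10&nbsp;°C and ceiling
37.8&nbsp;°C by default, clamping `tmax` and `tmin` **separately** into
`[base, ceiling]` before averaging — the standard capped-GDD convention —
so the daily value is bounded by `ceiling - base` = 27.8 and is monotone in
both temperatures. `day_length()` is astronomical: solar declination from
the fractional-year series with sunrise/sunset at zenith 90.833°, clamped
to $[0, 24]$ beyond the polar circles; a `day_length` column in the
weather table takes precedence when supplied. Photothermal time (PTT) is
daily GDD × day length.

`window_index()` aggregates daily values over a window of days after
planting, planting day being day 0 (so "18–43 d after planting" spans the
26 calendar days from planting+18 through planting+43). Aggregation is the
**mean** of daily values by default so that windows of different lengths
are comparable during a search; a `"sum"` switch is exposed because
accumulated totals are also common. `window_search()` scans a start × end
grid, correlating each candidate window's indices across environments with
the observed environmental means, and returns the full surface plus the
window maximizing $|r|$ (ties: earliest start, then shortest window). At
least three environments are required — a correlation over two points is
meaningless.

## Simulated environmental variability

`build_env_grid()` expands per-site planting windows into a deterministic
(site, year, planting date) grid. The bundled `sorghum_design()` uses 51
daily dates per window — 21 May–10 July for the three summer sets, and
1 December–20 January for the winter set — over seven years and four
site-sets, giving 4 × 7 × 51 = 1428 environments; a stated 50-date window
is inconsistent with that total and with the 21 May–10 July span, which is
51 days inclusive, so 51 is used and both windows are configurable.
`rice_design()` gives 6 × 3 × 93 = 1674. Winter and summer plantings at the
same location are deliberately distinct "sites" because they sample
distinct parts of the seasonal cycle.

`partition_variance()` uses sequential (Type-I) sums of squares via
`stats::lm`/`stats::anova` with the order site → year → planting date (and
year → date within a site). On the balanced factorial grid the sequential
shares are order-invariant, which the tests verify, so nothing hinges on
the ordering; shares are affine-invariant in the index values.
`site_distributions()` summarizes per-site index values and computes kernel
densities on a shared grid, with optional merging of geographically
overlapping site groups.

Applying one index family and window to all simulated environments assumes
the index transfers unchanged across sites, years and dates — a stated
working assumption, not a finding.

## The synthetic-data generator

The generator exists so that every stage is testable without any download;
it emulates the *statistical shape* of a biparental flowering-time study:

* `simulate_biparental_genotypes()`: markers evenly spaced on each
  chromosome (default 10 chromosomes of 100 cM); genotypes follow a Markov
  chain along the chromosome with switch probability from Haldane's map
  function, $r = (1 - e^{-2d/100})/2$, with the RIL adjustment
  $R = 2r/(1+2r)$ for the recombination accumulated over selfing. RILs are
  fully homozygous (codes ±1, allele frequency 1/2). BILs use a copy/redraw
  chain with stationary genotype probabilities 0.70/0.10/0.20
  (recurrent homozygote / heterozygote / donor homozygote), matching the
  expected 75/25 allele skew toward the recurrent parent while retaining
  residual heterozygosity; the redraw probability uses the same
  distance-driven $R$, which reproduces decaying linkage without modelling
  the full backcross pedigree.
* `simulate_study()`: $\mu_i$ and $\beta_i$ are baselines plus sparse
  additive effects at (by default) disjoint QTL sets, so intercept and
  slope prediction accuracies are separately meaningful; $I_j$ is evenly
  spaced and centered; $\delta_{ij}$ is iid Gaussian.
* `simulate_weather()`: daily mean = site baseline (declining 0.43&nbsp;°C
  per degree of latitude from 27&nbsp;°C) + seasonal sinusoid with
  amplitude 0.35&nbsp;°C per degree of |latitude| (phase flipped in the
  southern hemisphere) + a site-year shift (sd 0.8&nbsp;°C) + daily noise
  (sd 2&nbsp;°C); `tmax`/`tmin` are ±5&nbsp;°C around the mean.

Default trait scale mirrors a sorghum flowering-time study measured in GDD:
baseline intercept 2000 GDD; environment means spanning 950 GDD (the
empirical spread was roughly 1507–2460 GDD); residual sd 60 GDD; population
mean slope 1 with sd($\beta$) ≈ 0.22 (10 QTL of effect sd 0.07), within
the plausible 0.6–1.4 spread of Finlay–Wilkinson slopes and large enough
that whole-set slope estimates (standard error ≈ 0.065 under these
conditions) correlate above 0.9 with the truth; sd($\mu$) ≈ 126 GDD
(10 QTL of effect sd 40). The default scale for routine testing is 64
lines × 200 markers × 9 environments; `synthetic_study("full")` switches
to the study-shaped 237 × 1462 × 9.

What the generator does **not** emulate: nonlinear reaction norms,
epistasis or G×E beyond the linear model, marker ascertainment and missing
data patterns of real genotyping, local weather shocks, or
latitude-dependent *interannual* variability (site-year shifts share one
sd across sites). The last point means the high-latitude > tropical spread
of window indices emerges for broad spring windows (where the seasonal
curve is steep) but can invert for windows centered on the flat midsummer
peak; tests of that property use broad windows, and conclusions about
specific real sites should come from real weather. Passing tests therefore
demonstrate correctness of the estimators and the directional
range/sample-size effects under the linear model — not that any particular
field trial matches the defaults.

## Problem sizes and determinism

Routine tests and the acceptance script run at the 64 × 200 × 9 scale with
a 40-subset sample for the subset-trained cross-validation scan and
20-replicate parameter-recovery simulations — sizes chosen to exercise
every code path with comfortable statistical margins while keeping a full
run in the low minutes. All generators are pure functions of (configuration,
seed): identical seeds give bit-identical phenotypes, genotypes and
weather, and fold seeds are recorded in every cross-validation result.

## Known limitations

* Linear reaction norms only; no random-coefficient or stability-variance
  alternatives.
* The environmental-index search scans one variable family (GDD or PTT)
  over rectangular windows; no multi-variable discovery.
* Sequential variance partitioning reports shares, not significance tests.
* Subset enumeration is exhaustive, not a search; beyond ~15 environments
  the $2^n$ growth makes a full scan impractical.
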