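---
title: "Methods: spatiotemporal analysis of search-index panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of search-index panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchscape)
```

`searchscape` analyses monthly, region-level search-volume indices as a
proxy for disease burden. This vignette documents the statistical models
the package implements, the parameters that matter, the behaviour of the
synthetic-data generator the tests rely on, and the numerical choices made
where the methodology leaves room.

## The data model

The central object is a long panel: one non-negative index value per
(region, month). Search indices are *relative* volumes on an arbitrary
scale, strictly positive in practice, with multiplicative structure — a
region twice as populous or a season twice as active scales the index, it
does not shift it. All temporal modelling therefore happens on the log
scale, and the panel is reduced to calendar months (daily or weekly records
are averaged on reading) because months are the finest unit at which both
the seasonal analysis and typical external prevalence series are defined.

### Cleaning

Platform extracts contain spikes (media events, scraping artifacts) and
gaps. `clean_panel()` applies, per region:

1. **Outlier flagging** by robust z-score `|x − median| / (1.4826 · MAD)`
   exceeding `outlier_z` (default 4 — conservative; a Gaussian series
   crosses 4 robust SDs with probability ≈ 6×10⁻⁵). A flat series has
   MAD 0; any value off the median is then treated as infinitely outlying.
2. **Imputation** of interior missing runs no longer than `max_gap`
   (default 2 months) by linear interpolation. Longer runs and missing
   endpoints stay missing and are reported — inventing half a year of data
   would manufacture seasonality.
3. **Region exclusion** below 24 non-missing months, the minimum the
   decomposition needs.

Both parameters are exposed rather than fixed: the flagging rule is a
package choice, not part of the method's identity, and every change is
listed in the returned report so the cleaning is auditable. The order
(outliers first, then gaps) makes the result independent of the record
order within a region.

## Temporal decomposition

`stl_decompose()` fits the multiplicative model `x_t = T_t · S_t · R_t` by
running additive STL — Cleveland's iterated loess procedure, via
`stats::stl()` — on `log x_t` and exponentiating back. The log transform
also stabilises the variance of a series whose level grows over time.
Choices:

- **Seasonal smoother**: `s.window = 13` (odd, about one year of
  cycle-subseries points either side), locally constant (`s.degree = 0`).
  A degree-0 subseries smoother is deliberately stiff: on pure noise it
  absorbs little variance, so the seasonal-strength null behaves (see
  below). The window is finite rather than periodic so slow drift of the
  seasonal shape remains representable.
- **Inner iterations**: 10, i.e. the inner loop is run to near-convergence
  rather than the customary 2. This matters for a clean separation: on a
  trend-only series, two iterations leave ~0.3% of the trend in the
  seasonal; ten leave < 10⁻⁶ (a property the tests assert).
- **Robustness**: off by default; `robust = TRUE` adds 2 outer
  (lowness-weighting) iterations for series with residual spikes.
- **Normalisation**: after fitting, the log-seasonal is re-centred to mean
  zero over every full 12-month window (the shift is absorbed into the
  trend), so the seasonal factors have geometric mean 1 per year and the
  trend carries the level. The remainder is recomputed as
  `log x − log T − log S`, making the closure `T·S·R = x` exact to
  machine precision by construction.
- **Diagnostics**: a Shapiro–Wilk p-value on the log remainder is attached;
  an approximately normal log remainder supports the multiplicative model.

Series must be strictly positive (the function refuses zeros and points the
caller to cleaning) and at least two full periods long. At exactly two
periods — the admissible minimum, where `stats::stl()` declines — a
single-pass fallback is used: loess trend (span 0.75, degree 1) alternated
twice with a periodic (cycle-mean) seasonal. It is the same model class,
with the seasonal constrained to be periodic, which is all two cycles can
identify anyway.

### Strength scores and peaks

`strength()` computes, on the **log-scale** (additive) components with
population variances,

$$F_T = \max\!\left(0,\, 1 - \frac{\mathrm{Var}(R_t)}{\mathrm{Var}(T_t + R_t)}\right),
\qquad
F_S = \max\!\left(0,\, 1 - \frac{\mathrm{Var}(R_t)}{\mathrm{Var}(S_t + R_t)}\right),$$

clamped to [0, 1]; `F_S ≥ 0.4` flags a seasonal series — the conventional
screening threshold for these variance-ratio features. Degenerate inputs
are defined explicitly: if the denominator variance is numerically zero
relative to the series (an exactly-decomposed constant or trend-only
series), the score is 0, not 0/0.

`seasonal_peak()` reports the per-calendar-month mean seasonal factor (the
numbers behind a subseries plot) and operationalises the "peak period" as
the months in the **top tercile** of the twelve mean factors **and** above
1 (with a 10⁻⁹ relative guard so numerically flat seasonals never peak).
The tercile rule captures a peak *period* of about a season's length; the
">1" condition prevents a flat or trough-dominated year from reporting
peaks at all.

Two orderings the methodology leaves open are exposed rather than decided:
optional pre-smoothing (`ses_smooth()`, the recurrence
`s_t = αx_t + (1−α)s_{t−1}`, default span `k = 7` i.e. `α = 2/(k+1) =
0.25`) can be applied before decomposition via `ses_alpha`, and strengths
can be computed on raw or smoothed series; defaults decompose the raw
(cleaned) series, since smoothing before STL transfers remainder variance
into the trend and inflates `F_T`.

## Spatial statistics

All spatial statistics consume a `spatial_weights` structure from
`build_weights()`. Defaults follow common GIS practice and are flags, not
constants, because studies rarely report their weights: **queen contiguity,
row-standardized** for Moran's I and LISA; a **fixed distance band with
self-inclusion** for Gi\* (the \*-variant is defined with the self term;
the band's auto-threshold is the smallest radius leaving no region
neighbourless). Contiguity is derived from shared polygon boundary vertices
snapped to 10⁻⁸; queen needs one shared vertex, rook two (an edge on
well-noded boundaries). Islands are kept with zero rows and reported.

- **Global Moran's I** follows the cross-product form with deviations from
  the mean; the analytic z and two-sided p use the randomization
  (non-free-sampling) variance. The permutation p is
  `(1 + #{|I* − E[I]| ≥ |I − E[I]|}) / (n_perm + 1)` over `n_perm`
  relabellings (999 by default) from a seeded Mersenne-Twister stream, so
  results are reproducible across platforms. Constant fields are refused:
  the statistic is undefined.
- **Local Moran's I** uses the row-standardized lag; inference is by
  *conditional* permutation (region i's value held fixed, neighbours drawn
  from the remaining n−1 values), two-sided around the conditional
  expectation `−z_i²Σw_ij/((n−1)m₂)`. Labels come from the quadrant of
  `(z_i, lag_i)` when `p ≤ alpha` (default 0.05); a lag of exactly zero is
  Not significant. With row-standardized weights the `I_i` average exactly
  to global I — an identity the tests check to 10⁻⁹. Note a structural
  limit of conditional permutation: an outlier among otherwise
  exchangeable-looking values (e.g. one low cell whose value set contains
  no other low values to place nearby) cannot reach significance, because
  every rearrangement looks alike.
- **Getis-Ord Gi\*** uses the standard z formulation with the global
  (population) SD; bins follow the conventional confidence cut-offs
  ±1.645/±1.960/±2.576. Optional Benjamini–Hochberg demotion additionally
  requires the BH-adjusted two-sided normal p to support each bin's level;
  it only ever demotes. It is off by default.
- **Standard deviational ellipse**: weighted mean centre; azimuth from the
  classic GIS rotation formula (reported in degrees clockwise from north,
  in [0, 180)); axis lengths are the weighted SDs along the rotated axes at
  level 1 SD (no √2 inflation). Collinear or coincident points yield a
  degenerate ellipse (zero axis) with a warning rather than an error, since
  a degenerate directional summary is still informative.

## Ordinary kriging

The kriging chain mirrors standard geostatistical practice:

1. `remove_trend()` — least-squares polynomial surface of order 0–2
   (monomials of {1, x, y, x², xy, y²}); kriging then works on residuals
   and predictions re-add the trend. Second-order removal is the default in
   the pipeline because regional index fields typically show a broad
   east–west gradient that would otherwise masquerade as long-range
   spatial dependence.
2. `empirical_semivariogram()` — the method-of-moments estimator over
   equal-width bins on `(0, max_lag]`; defaults 12 bins to half the maximum
   pairwise distance (beyond half the extent, pairs are few and estimates
   unstable). The pipeline widens to the full range if fewer than four
   distinct bins are populated, as happens on small lattices with few
   distinct distances.
3. `fit_variogram()` — weighted least squares with weights `N(h)/h²`
   (short, well-populated lags dominate), non-negativity bounds via
   L-BFGS-B, and three range starts (⅓, ⅔, 1 × max lag) to avoid local
   minima; the best feasible point is returned with a warning if the
   optimizer does not report convergence. The spherical family is the
   default (the common GIS default); exponential and gaussian use the
   practical-range convention (95% of the sill at `a`).
4. `ordinary_krige()` — per grid node, the OK system (semivariance matrix
   bordered by the unbiasedness row) is solved with a single factorisation
   and all nodes as right-hand sides; weights sum to 1, predictions are
   exact at data points under nugget-free models, and the kriging variance
   `Σλγ + μ` is clipped at 0 to absorb round-off no larger than 10⁻⁹.
   Coincident points are averaged first with a warning. Surfaces are
   cell-centre registered and written as ESRI ASCII grids (6-decimal
   round-trip).
5. `loo_cross_validate()` — leave-one-out re-prediction reporting RMSE,
   mean error and the mean standardized error (error / kriging SD), the
   usual check that the fitted variogram's scale is believable.

Coordinates are assumed planar throughout; geographic coordinates must be
projected first — the package performs no projection.

## The synthetic-data generator

Because platform extracts are proprietary, `generate_panel()` provides a
test bed with the structure the analysis assumes:

$$x_{rt} = \mathrm{base} \cdot (1+\mathrm{trend})^{(t-1)/12} \cdot a_{m(t)}
\cdot G_r \cdot \varepsilon_{rt}$$

with month-of-year amplitudes `a` (geometric mean 1), a region effect
`G_r` combining a deterministic multiplicative east–west gradient with a
rook-neighbour-smoothed lognormal effect (one smoothing round with weight
`spatial_rho` — cheap, induces positive Moran's I, and easy to reason
about, unlike a full simultaneous-autoregressive solve), and lognormal
noise with mean 1 and coefficient of variation `noise_cv`. The random
region effects share `noise_cv`, so a noiseless configuration is exactly
deterministic.

Defaults define the study conditions: a 6 × 5 grid (about the number of
provincial units of a large country), 9 years of monthly data from 2014,
base level 100, 8%/year growth, a March–May amplitude peak of 1.25 before
renormalisation, gradient 15% per unit x, `spatial_rho = 0.5`,
`noise_cv = 0.1`. `generate_prevalence()` derives an annual series as a
strictly monotone, log-compressed transform of the national annual mean
(bounded growth keeps it positive and finite under any noise), perturbed
before the transform by Gaussian noise so the rank agreement degrades
smoothly as the noise grows; the pipeline's default perturbation (5% of the
base level) yields a strongly but imperfectly rank-correlated series, as an
external burden series would be. `generate_demand_terms()` emulates a
seasonal top-terms table whose lead self-treatment query holds ≈30% of the
top-8 volume, boosted in winter.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real extracts: platform normalisation artifacts and
level changes, internet-penetration and population confounding, daily and
weekly microstructure, aggregation of city indices into provincial ones
(regions are independent units; whether a platform sums or averages
sub-regions is unknowable from outside), and media-event spikes beyond what
the lognormal tail produces.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and uses R's default
Mersenne-Twister stream; equal (inputs, config, seed) give byte-identical
tabular outputs, which the tests assert by comparing files from two
independent runs. The pipeline records the resolved configuration including
the seed next to its outputs.

The test suite works at deliberately compact sizes chosen to exercise every
code path while keeping a full run interactive: lattices of 4×4–6×6 for
the oracle-equivalence and calibration checks (1000 independent-field
simulations at 199 permutations for the Moran test's size), 100 generator
seeds for the gradient-recovery power check, 15×15 Cholesky-simulated
Gaussian fields for variogram parameter recovery, and the full default
study (30 regions × 108 months, 999 permutations) for the end-to-end
determinism check. Variogram fitting on single realisations is noisy by
nature; the recovery criterion (range within 30% of truth in ≥ 70% of
seeds) reflects that rather than any weakness of the optimizer.

## Known limitations

- Contiguity detection is vertex-based; polygons whose shared borders are
  digitised with non-matching vertices need a `snap` large enough to merge
  them, or distance-based weights.
- Exact Spearman p-values stop at n = 10 (10! ≈ 3.6M orders); beyond that
  the t-approximation is reported with `p_exact = NA`, and ties always fall
  back to the approximation.
- The kriging solver is dense; it is meant for hundreds of support points
  (city-level panels), not tens of thousands.
- No space–time statistics: the spatial analyses operate on one per-region
  scalar (the pipeline's default is the mean over a configurable year
  list), mirroring year-by-year practice rather than a joint model.
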