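# searchscape

Spatiotemporal analysis of disease-related search-index panels.

## What it is for

Search engines publish relative query-volume indices (Baidu Index, Google
Trends) that track, month by month and region by region, how often the
public looks up a disease term. Such series are a cheap proxy for disease
burden: validated against an external prevalence series, they support
*infodemiology* — inferring seasonal patterns and regional disparities of a
condition from search behaviour, without surveys or registries.

`searchscape` packages the full analysis such a study requires, for anyone
holding a long-format `(region, month, index)` panel plus region polygons:

- **Temporal structure** — simple exponential smoothing; multiplicative STL
  decomposition (additive STL on the log scale), `x_t = T_t S_t R_t`;
  trend- and seasonal-strength scores

  `F_T = max(0, 1 − Var(R_t)/Var(T_t + R_t))`,
  `F_S = max(0, 1 − Var(R_t)/Var(S_t + R_t))`,

  computed on the log-scale components, with `F_S ≥ 0.4` marking a seasonal
  series; seasonal-peak months from the subseries factors.
- **Spatial structure** — queen/rook/knn/distance-band spatial weights;
  global Moran's I with analytic (randomization) and permutation inference;
  local Moran's I (LISA) with conditional-permutation p-values and
  High-High / Low-Low / Low-High / High-Low labels; Getis-Ord Gi\* hot- and
  cold-spot bins at the ±1.645/1.960/2.576 z cut-offs (optional FDR
  demotion); the standard deviational ellipse (direction of the
  distribution).
- **Geostatistics** — empirical semivariogram, spherical / exponential /
  gaussian variogram fits (weighted least squares, `N(h)/h²` weights),
  polynomial (up to second-order) trend removal, ordinary kriging with
  prediction variance onto ESRI ASCII grids, leave-one-out
  cross-validation.
- **Validation & demand** — Spearman correlation of the annual national
  index against a prevalence series, with *exact* enumeration p-values for
  n ≤ 10; seasonal top-8 demand-term share tables.
- **Synthetic data** — a generator producing region grids, multiplicative
  trend × month-of-year × spatial-gradient × lognormal-noise panels, and
  rank-correlated annual prevalence series, so the whole pipeline can be
  exercised and tested without proprietary platform extracts.

All coordinates are abstract planar units: project geographic data before
use.

## Worked example

```r
library(searchscape)

cfg     <- panel_config(seed = 1)        # 6 x 5 regions, 9 years monthly
regions <- generate_geometry(6, 5)
panel   <- generate_panel(cfg, regions)

decs <- decompose_panel(panel)           # per-region + national STL
strength(decs$national)
#> F_T = 0.9926, F_S = 0.9683  (seasonal: F_S >= 0.4)
seasonal_peak(decs$national)$peak_months
#> [1] 3 4 5

W <- build_weights(regions, "queen", row_standardize = TRUE)
v <- as.numeric(tapply(panel$value, panel$region_id, mean)[region_ids(regions)])
global_morans_i(v, W, n_perm = 999, seed = 1)
#> Global Moran's I = 0.6503 (E[I] = -0.03448)
#>   z = 6.893, analytic p = 5.472e-12, permutation p = 0.001 (999 permutations)

prev <- generate_prevalence(panel, rank_noise = 5, seed = 2)
spearman(as.numeric(tapply(panel$value, panel$year, mean)), prev$value)
#> Spearman rho = 0.9833 (n = 9)
#>   exact two-sided p = 4.96e-05, asymptotic p = 1.936e-06
```

Reading the output: the national series is strongly trended and clearly
seasonal (`F_S = 0.97 ≥ 0.4`), peaking in March–May — the spring peak the
generator builds in. The regional yearly means are strongly spatially
clustered (Moran's I = 0.65 against an expectation of −0.034 under no
autocorrelation; none of 999 permutations came close, p = 0.001). The
synthetic prevalence series tracks the annual national index up to one
swapped pair of years (ρ = 0.983; the exact two-sided p over all 9! rank
orders is 4.96 × 10⁻⁵).

The full study — cleaning, decomposition, per-year Moran table, LISA, Gi\*,
ellipse, kriging, validation, demand shares — runs as one call writing CSV,
GeoJSON and `.asc` artifacts:

```r
cfg <- default_config(); cfg$out_dir <- "output"
stage_report(cfg)
```

or from a shell via the thin wrapper
`inst/scripts/searchscape-cli.R <subcommand> [config-file]` (subcommands
`simulate … report`; flat `key = value` config, see `?default_config`).

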