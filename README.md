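# nescoast

Composite assessment of coastal sustainable development, for analysts who
score regions or countries on hierarchical natural–economic–social (N-E-S)
indicator systems and then ask *where* sustainability clusters in space and
*which* subsystems drive the differences.

The package implements the full analysis chain as composable,
pipe-friendly functions over data frames:

- **Hierarchical composite scoring** — a three-tier evaluation hierarchy
  (3 themes / 7 sub-themes / 29 indicators in the bundled default), min–max
  normalization with direction handling, and weighted aggregation to
  sub-theme, theme, and composite (CSDI) scores on a 0–100 scale, with
  configurable or entropy-method weights.
- **Coupling coordination** — the three-subsystem model
  `C = [U₁U₂U₃ / ((U₁+U₂+U₃)/3)³]^{1/3}`, `T = Σ αᵢUᵢ`, `D = 100·√(C·T)`,
  summarizing balance (C) and joint level (D) of the natural, economic, and
  social theme scores.
- **Global Moran's I** — `I = ΣᵢΣⱼ Wᵢⱼ(Yᵢ−Ȳ)(Yⱼ−Ȳ) / (S² ΣᵢΣⱼ Wᵢⱼ)` with
  population variance `S²`, spatial weights from lattice contiguity,
  k-nearest neighbours, inverse distance, or explicit edge lists, and
  permutation inference (999 randomizations by default, add-one p-value).
- **Geographical detector** — the factor detector
  `q = 1 − Σₕ Nₕσₕ² / (Nσ²)` with noncentral-F and permutation
  significance, and the interaction detector with its five-way
  classification (independent / nonlinear-enhance / bivariate-enhance /
  uniform-weaken / nonlinear-weaken).
- **Exact Jenks natural breaks** — Fisher's dynamic-programming optimum for
  mapping scores into interval classes I, II, III, IV.
- **A synthetic panel generator** — country-style panels with known
  regional clustering, theme-driven variance shares, direction-mixed
  indicators, and missingness, so the whole pipeline is testable against
  ground truth.

## A worked example

Simulate a 41-country, three-period panel at the default study conditions
and run the end-to-end pipeline (normalize → aggregate → coupling → Moran
→ geodetector → Jenks classes):

```r
library(nescoast)

sim <- simulate_panel(sim_config(seed = 42))
res <- run_csd_pipeline(sim$panel, sim$hierarchy, sim$coords,
                        n_perm = 999, seed = 1, quiet = TRUE)

res$moran
#> # A tibble: 3 × 6
#>   period     I expected_I p_perm     n n_islands
#>   <chr>  <dbl>      <dbl>  <dbl> <int>     <int>
#> 1 2010   0.273     -0.025  0.005    41         0
#> 2 2015   0.167     -0.025  0.04     41         0
#> 3 2020   0.254     -0.025  0.007    41         0
```

The composite score clusters spatially (I ≈ 0.17–0.27 against a null
expectation of −1/(n−1) = −0.025, permutation p ≤ 0.04 in all three
periods): the generator placed countries in five regional clusters with
correlated latent scores, and the statistic recovers it.

```r
res$detector$factors
#> # A tibble: 8 × 5
#>   driver           q     F     p     m
#> 1 natural      0.684  63.9     1     5
#> 2 economic     0.699  68.5     1     5
#> 3 social       0.637  51.8     1     5
#> 4 atmosphere   0.591  42.6     1     5
#> ...
```

Factor-detector q values say each theme explains 60–70% of the spatial
variance of the composite (the economic theme leading, matching the
generator's variance shares of 0.45/0.35/0.20 for
economic/social/natural). Interactions are enhancing:

```r
head(res$detector$interactions, 2)
#> # A tibble: 2 × 6
#>   x1      x2          q1    q2   q12 category
#> 1 natural economic 0.684 0.699 0.878 bivariate-enhance
#> 2 natural social   0.684 0.637 0.895 bivariate-enhance
```

and the entity-mean composite maps into four Jenks classes:

```r
attr(res$classes, "breaks")
#> Jenks natural breaks: k = 4, GVF = 0.8943
#>   I[15.46-27.97] (n=4)  II[33.48-43.63] (n=15)  III[45.48-55.2] (n=14)  IV[58.71-78.39] (n=8)
```

Individual pieces work standalone and return tidy tibbles — for example
the factor detector's defining anchors:

```r
q_statistic(1:6, rep(c("a", "b"), each = 3))
#> Geodetector q = 0.7714 (N = 6, m = 2 strata), F = 13.5, p = 0.7721 [ncF]

coupling_coordination(0.2, 0.4, 0.6)
#> # A tibble: 1 × 3
#>       C     T     D
#> 1 0.909   0.4  60.3
```

`tidy()`/`glance()` methods cover the fitted objects (`moran_test`,
`q_result`, `interaction_result`, `jenks_breaks`), and `autoplot()` draws
score trajectories, permutation distributions, and class intervals.

See `vignettes/coastal-sustainability-methods.Rmd` for the model,
assumptions, parameter meanings, and numerical conventions.

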