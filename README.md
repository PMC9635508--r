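# grainfill

Richards growth-curve analysis of rice grain filling.

`grainfill` is for agronomists and crop physiologists working with grain
dry-weight time series — typically superior and inferior grains sampled
every few days after panicle labeling. It fits the four-parameter Richards
growth equation to each series, derives the kinetic characteristics of the
filling process in closed form, decomposes the filling period into start /
middle / late sub-phases at the inflection points of the rate curve, and
correlates the characteristics with yield components and grain-quality
traits. A synthetic-data generator emulating a two-site, two-year field
study at high latitudes makes every stage testable without field data.

## The model

Grain dry weight after anthesis follows the Richards (generalised logistic)
law

```
W(t) = A (1 + B e^{-Kt})^{-1/N}
```

with final grain weight `A` (mg), position constant `B`, rate constant `K`
(day⁻¹) and shape parameter `N` (the logistic at `N = 1`). Its derivative is
the grain-filling rate GFR(t), and the standard filling characteristics
follow in closed form:

| quantity | formula | meaning |
|---|---|---|
| `R0` | `K/N` | initial relative growth rate |
| `GFR_max` | `A·K·(1+N)^{-(N+1)/N}` | maximum filling rate (mg grain⁻¹ day⁻¹) |
| `T_max` | `(ln B − ln N)/K` | time of the rate peak (days) |
| `W_max` | `A·(N+1)^{-1/N}` | weight at the rate peak (mg) |
| `GFR_avg` | `A·K / (2(N+2))` | average filling rate |
| `GFD` | `t : W(t) = 0.99·A` | active grain-filling duration |
| `t1`, `t2` | roots of `u² − N(N+3)u + N² = 0`, `t = (ln B − ln u)/K` | rate-curve inflections bounding the middle sub-phase |

The fractions of `A` accumulated before `t1`, between `t1` and `t2`, and
after `t2` are the start/middle/late sub-phase contributions; the middle
share depends on `N` only and sits near 60% for typical fits.

## Worked example

```r
library(grainfill)
library(dplyr)

# a published superior-grain parameter set (Suijing-18, Harbin, 2017)
params <- richards_reference_params() |>
  filter(cultivar == "Suijing-18", site == "Harbin",
         year == 2017, grain_class == "superior")
filling_characteristics(params) |>
  select(R0, GFR_max, T_max, W_max, GFR_avg, GFD, frac_middle) |>
  as.data.frame()
#>          R0  GFR_max    T_max    W_max  GFR_avg      GFD frac_middle
#> 1 0.4363636 1.598995 13.42409 10.32684 1.078118 32.57985   0.5965072
```

The rate peaks at 13.4 days after labeling at 1.60 mg grain⁻¹ day⁻¹, when
the grain holds 10.3 of its final 22.9 mg; active filling lasts ~33 days,
and the middle sub-phase between the two rate-curve inflections contributes
59.7% of final grain weight.

A full synthetic study — simulate 32 series, refit them, and test how the
characteristics relate to simulated traits:

```r
sc     <- default_scenario(seed = 7)        # 4 cultivars x 2 sites x 2 years x 2 grain classes
series <- simulate_series(sc)               # 320 noisy observations
fit    <- fit_richards(series, seed = 7)    # bounded multi-start NLS
glance(fit)                                 # per-series R^2, SSE, warnings
traits <- simulate_trait_table(sc)
trait_correlations(inner_join(fit$fits, traits),
                   x_cols = c("GFR_avg", "GFD"),
                   y_cols = c("grain_yield_kg_ha", "chalkiness_pct"))
#> # A tibble: 4 x 7
#>   x_name  y_name                  r  p_value     n significant controls
#>   <chr>   <chr>               <dbl>    <dbl> <int> <lgl>       <chr>
#> 1 GFR_avg grain_yield_kg_ha  0.392  2.65e- 2    32 TRUE        ""
#> 2 GFR_avg chalkiness_pct     0.496  3.90e- 3    32 TRUE        ""
#> 3 GFD     grain_yield_kg_ha -0.908  7.20e-13    32 TRUE        ""
#> 4 GFD     chalkiness_pct    -0.962  2.07e-18    32 TRUE        ""
```

`autoplot(fit)` draws the fitted curves over the observations;
`plot_filling_rates(fit)` draws the rate curves with `t1`, `T_max`, `t2`
marked. `run_pipeline(pipeline_config(...))` chains the whole analysis from
CSV input to CSV/JSON output, and `inst/cli/grainfill.R` exposes it as a
command-line tool.

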