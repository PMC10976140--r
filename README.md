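# lurok

Hybrid land-use-regression / ordinary-kriging exposure models for ambient
air pollution, with leave-one-site-out cross-validation and
population-weighted exposure comparison between model families.

## What it is for

Health studies need NO2 and PM2.5 concentrations at every home on a
kilometre grid, but a city monitors at a few dozen stations. The standard
answer is land-use regression (LUR): regress monitored concentrations on
geographic covariates (population density, roads, land use, vegetation,
coordinates) that are known everywhere, then predict off-network. Because
LUR residuals are spatially correlated, a second stage interpolates them
by ordinary kriging (OK); the hybrid prediction is

```
ĉ(s) = LUR(x(s)) + OK(residuals)(s)
```

`lurok` implements this pipeline for three LUR families under a common
fit/predict contract —

* **PLS**: partial least squares (NIPALS, 3 latent scores by default),
* **RF**: random forest (`mtry` 50, 500 trees, node size 5, permutation
  IncMSE-style importance),
* **SLR**: supervised stepwise linear regression (forward selection by
  R² gain ≥ 0.1 with expected-sign plausibility, then iterative removal
  until all VIF ≤ 3),

— plus the stages around them: hierarchical temporal averaging of hourly
monitor data under completeness criteria (≥ 12 h per day, ≥ 3 days per
week, ≥ 25% of weeks per year, long-term mean over available years),
Matheron empirical variograms with weighted-least-squares model fitting,
leave-one-site-out cross-validation (LOOCV) with

```
RMSE   = sqrt(mean((y - ŷ)²))
R²_mse = max(0, 1 − RMSE² / var(y))      # fit to the 1:1 line
R²_reg = cor(y, ŷ)²                      # fit to the regression line
```

refitting every model component inside each fold, 1-km gridded
prediction, and population-weighted exposure quartile misclassification
between models. A seeded synthetic-data generator reproduces the study
structure (a 35-site network: 1 background, 7 traffic, 14 urban,
13 suburban; six hourly years with realistic missingness; a 3301-cell
1-km population grid totalling 15.94 million people in [211, 32097]
persons/km²) so the whole pipeline runs and is tested without proprietary
monitoring or GIS data.

## Worked example

```r
library(lurok)

cfg   <- sim_config(years = 2015:2016, n_grid_cells = 900,
                    pop_total = 4e6, seed = 42)
study <- simulate_study(cfg)          # network, covariates, hourly, grid

agg    <- aggregate_concentrations(study$hourly)
y      <- setNames(agg$ltm$value, agg$ltm$site_id)[study$network$site_id]
coords <- as.matrix(study$network[, c("x", "y")])

loocv("PLS", study$covariates, y, coords)
#> <lurok LOOCV: PLS, n = 35>
#>   RMSE 3.306  R2_mse 0.896  R2_reg 0.898
loocv("PLS", study$covariates, y, coords, kriging = TRUE)
#> <lurok LOOCV: PLS-OK, n = 35>
#>   RMSE 2.864  R2_mse 0.922  R2_reg 0.926

hyb <- fit_hybrid("PLS", study$covariates, y, coords)
hyb$variogram
#> <exponential variogram: nugget 0, partial sill 6.349, range 7323 m>

surf <- predict_surface(hyb, study$grid)
population_weighted_mean(surf, study$grid)
#> [1] 37.11
quartile_classify(surf, study$grid)$cutpoints
#> [1] 28.84 39.54 44.77
```

Reading the output: held-out PLS predictions explain ~90% of the
between-site variance on the 1:1 scale, and adding the kriging stage
lifts R²_mse to 0.92 because the generator's residual field is spatially
correlated (the fitted variogram recovers a range of ~7 km against a
generating 12 km on 35 sites). The population-weighted long-term exposure
under this model is 37.1 µg/m³, and the person-level quartile cutpoints
are the three printed concentrations.

The full orchestration — simulate, aggregate, six model variants of
LOOCV per period, surfaces, misclassification/COV/correlation — runs from
one config:

```r
man <- run_pipeline(demo_run_config(seed = 1), "out/")
```

and writes `cv_metrics.csv`, per-model `surface_*.csv`,
`misclassification.json`, `cov.csv`, `correlation.csv` and a checksum
manifest. A thin command-line wrapper with `simulate`, `aggregate`,
`fit`, `cv`, `predict`, `compare` and `run-all` subcommands is installed
at `inst/cli/lurok.R`.

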