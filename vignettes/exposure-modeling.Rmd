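---
title: "Hybrid land-use-regression / kriging exposure models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid land-use-regression / kriging exposure models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological studies of ambient air pollution need concentration
estimates at places where nobody measures. Regulatory monitoring networks
are sparse — a few dozen stations for a megacity — while health analyses
assign exposure to people living on a kilometre grid. Land-use regression
(LUR) bridges the gap: regress monitored concentrations (here NO2 or
PM2.5, in µg/m³) on geographic covariates available everywhere —
population density, road network descriptors, land-use shares, vegetation
indices, coordinates — and predict from the covariates at unmonitored
locations. LUR residuals are rarely independent in space, so a second
stage interpolates them by ordinary kriging (OK); the hybrid LUR-OK
predictor is the LUR prediction plus the kriged residual.

`lurok` implements this two-stage pipeline end to end for three LUR
families under one fit/predict contract, evaluates them by
leave-one-site-out cross-validation (LOOCV), predicts exposure surfaces
over a population grid, and quantifies how much the *choice of model
family* shifts population-weighted exposure estimates — the quartile
misclassification that matters when exposure classes feed a health model.

## From raw hours to annual means

Monitors report hourly values with substantial missingness (instrument
downtime can last weeks). Averaging naively would let a well-sampled
winter dominate a sparsely sampled year, so aggregation is hierarchical
with completeness screens at every level:

* **day** = mean of present hours, kept only if ≥ 12 of 24 hours (50%)
  are present;
* **week** = mean of available days, kept only if ≥ 3 days are available;
* **year** = mean of available weeks, kept only if ≥ 25% of the ISO
  year's weeks (13 of 52, 14 of 53) are available;
* **long-term mean (LTM)** = unweighted mean of the site's available
  annual values; a site missing some years still contributes through the
  years it has.

Days are defined in the local standard time of the study domain
(configurable UTC offset, default +8). Weeks are ISO-8601 weeks assigned
to the ISO year of their Thursday: the convention is not dictated by the
averaging idea itself, but it is unambiguous and reproducible, which is
what a completeness rule needs. The 25% rule is read as
`ceiling(0.25 × weeks-in-year)` available weekly values — the smallest
integer count consistent with "at least 25%". No gaps are imputed
anywhere: missing stays missing, and tightening any screen can only
reduce the number of available aggregates.

## The three regression families

All families consume a site × variable covariate matrix whose metadata
records an *expected sign* per variable (+, −, or unconstrained), and all
obey the same contract: `predict()` accepts any covariate set containing
the training columns, in any order.

**PLS** (partial least squares, `fit_pls()`): covariates are centered and
scaled, the response centered, and `n_scores` orthogonal latent scores
extracted by NIPALS to maximize covariance with the response; prediction
is the linear map back through the scores. The default of 3 scores is the
conventional choice for geographic covariate sets of this kind. PLS score
signs are arbitrary, so the first score is flipped, when necessary, to
correlate non-negatively with the response; that stabilizes the standard
diagnostic (`pls_score_correlations()`) of which covariates load on the
first score. With as many scores as (full-rank) covariates, PLS
reproduces ordinary least squares — a property the test suite uses as an
oracle.

**RF** (random forest, `fit_rf()`, via the `randomForest` package): 500
trees, minimum node size 5, and `mtry = 50` candidate variables per
split, the settings conventional for this application. When fewer than 50
covariates exist, `mtry` is clamped to the number available with a
warning rather than failing — the setting stays usable at any problem
size. Variable influence is reported as permutation importance
(`rf_importance()`): the increase in out-of-bag MSE when a variable is
permuted, in the IncMSE style. Forest predictions are averages of
training-leaf values and therefore can never leave the range of the
training response — worth remembering when a background site sits far
below every urban observation.

**SLR** (supervised stepwise linear regression, `fit_slr()`): forward
selection starting from the best sign-plausible univariate fit, adding in
each round the variable with the largest R² gain subject to every
sign-constrained coefficient keeping its expected direction, stopping
when the best gain falls below a threshold; then variables are removed
worst-first until all variance inflation factors (VIF = 1/(1−R²) of each
selected variable on the others) are ≤ 3, refitting after each removal.
The R²-gain default is 0.1, the printed convention for this procedure; it
is noticeably larger than the 0.01 used by ESCAPE-style protocols, so the
threshold is an explicit `slr_spec()` knob. Sign plausibility is enforced
on the entering variable and re-checked for all selected variables after
each addition; re-checking is stricter than the minimal reading of the
procedure but is the reproducible choice. The full selection trace
(entries, R² path, VIF removals) is stored on the model.

## Residual kriging

The residuals of the fitted LUR at the training sites are the kriging
support. Their spatial structure is summarized by the Matheron empirical
semivariogram — γ̂(h) = Σ(z_i − z_j)²/(2N(h)) over distance bins, 12 bins
to half the maximum inter-site distance by default — and fitted with a
parametric model (exponential by default; spherical and Gaussian
selectable) by weighted least squares with the standard N(h)/h² weights,
box-constrained to nonnegative variances and multistarted from
method-of-moments initial values. The exponential family is the default
because air-pollution residual variograms are typically rough at short
range; nothing in the two-stage structure depends on the choice, and the
family is a parameter.

Ordinary kriging solves the usual system (pairwise semivariances bordered
by the unbiasedness row) once for all targets; weights sum to one by
construction and are checked to 1e-8 on every solve. With a zero nugget
the predictor interpolates the support exactly, so the in-sample hybrid
reproduces the training observations; with a pure-nugget variogram the
kriging weights collapse to the stationary mean and the hybrid reduces to
the LUR (exactly so for the linear families, whose residuals average
zero). Negative hybrid concentrations are floored at zero with a count
attached — concentrations are physical quantities.

Numerical choices worth noting: distances are computed by direct
coordinate differences, not the cross-product expansion, because kriging
systems near exact interpolation are ill-conditioned and amplify any
distance round-off; the variogram optimizer parameters are scaled
(variances by the empirical sill, range by the maximum lag) and its
box-boundary output clamped; a flat empirical variogram yields a
pure-nugget model with a warning, and if every optimizer start diverges
the method-of-moments values are used with a warning rather than failing
a whole cross-validation fold.

## Validation

`loocv()` holds out one site at a time and refits *everything* on the
remaining sites: the LUR (including PLS centering/scaling constants) and,
when kriging is on, the residuals, the empirical variogram, the fitted
variogram and the kriging support. The held-out site contributes nothing
to its own prediction — any other arrangement leaks information and
flatters the hybrid exactly where it should be penalized. Pooled held-out
pairs yield:

* **RMSE** = √(mean (y − ŷ)²), in µg/m³;
* **R²_mse** = max(0, 1 − RMSE²/(population variance of y)) — fit to the
  1:1 line, clamped at zero;
* **R²_reg** = squared Pearson correlation — fit to the regression line.

R²_mse ≤ R²_reg always (the regression line is the best linear fit; the
1:1 line is not), and the clamp makes a predictor worse than the mean
score exactly zero rather than negative. Model comparison should lean on
R²_mse and RMSE; R²_reg is reported for comparability with studies that
quote it.

## Exposure assessment

Fitted hybrids predict at the centers of a 1-km population grid
(`predict_surface()`). The population-weighted exposure estimate (PEE) is
Σ pop·pred / Σ pop. Cells are classified into exposure quartiles where
the cutpoints are *person-level* quantiles: each person carries their
cell's exposure, and the 25/50/75% points are taken over persons, not
over cells ("population" weighting; a "grid" mode exists for
sensitivity). Ties at a cutpoint go to the lower quartile — the
cumulative-distribution convention — and the implementation agrees
exactly with a brute-force expansion to one row per person, which the
tests enforce. Quartile cutpoints are computed per model (each model's
own 25% bands), not from a pooled distribution; a pooled comparison would
conflate level differences with ranking differences.

`misclassification()` cross-tabulates the population shares of the 4×4
quartile combinations for two models and reports the total off-diagonal
share, the over- and under-estimated shares, and the non-adjacent share
(≥ 2 quartiles apart). `cross_model_cov()` reports the per-cell
coefficient of variation across models, using the sample (n−1) standard
deviation — three models are a sample — and `cross_model_correlation()`
the pairwise Pearson matrix.

## What the synthetic generator emulates — and what it does not

No real monitoring or GIS data ship with the package; `sim_config()` and
`simulate_study()` generate a study with the statistical structure the
pipeline assumes:

* a 35-site network (1 background, 7 traffic, 14 urban, 13 suburban) on
  an abstract 70-km planar domain in meters — urban and traffic sites
  clustered near the center, suburban peripheral, the background site
  maximally remote;
* 12 smooth spatial covariate fields (seeded random cosine expansions, so
  the same field evaluates consistently at sites and grid cells) of which
  4 carry nonzero coefficients (8, 6, −5, 4), plus the two coordinates as
  covariates; expected signs mirror the true coefficients;
* hourly concentrations = intercept (40 µg/m³) + Xβ + a spatially
  correlated residual (exponential covariance, sill 6 (µg/m³)², range
  12 km, nugget 0.5, simulated by Cholesky factorization at the site
  locations) + an annual sinusoid (amplitude 15 µg/m³, summing to zero
  exactly over each calendar year) + iid noise (sd 8 µg/m³), floored at
  zero;
* 15% missingness as a mixture of completely-at-random gaps and
  contiguous one-to-three-week outages, so each completeness screen has
  both passing and failing cases;
* a 3301-cell 1-km population grid, center-peaked with lognormal texture,
  densities clipped to [211, 32097] persons/km² and the total matched to
  15.94 million by solving a power transform of the density shape (so the
  clip bounds hold exactly after rescaling).

These values are the package's picture of a realistic six-year urban
monitoring study and are deliberately fixed as defaults; everything is a
`sim_config()` argument. What the generator does *not* emulate:
meteorology and chemistry (the seasonal term is a fixed sinusoid, not
weather), covariates derived from real GIS layers (buffered road lengths,
POI counts, NDVI rasters — the synthetic fields play the same statistical
role without the semantics), temporally varying spatial residuals, or any
real coordinate system. Passing tests therefore demonstrate that the
*methods* behave correctly under the assumed structure — not that any
particular real-world dataset would yield a particular R².

## Problem sizes used in the checks

The shipped tests run the generator at reduced scale (single simulated
years, grids of a few hundred cells, 20-seed repetitions for stochastic
properties) so the whole suite stays in the low minutes; the
`scripts/acceptance.R` run uses the full default study — 35 sites, six
hourly years, the 3301-cell grid, all six model variants under LOOCV —
and completes in a few minutes on one core. Kriging solves are vectorized
(one factorization per support set, all targets solved together), which
is what keeps 3301-cell surfaces cheap inside cross-validation loops.

## Known limitations

* Universal kriging, anisotropy and co-kriging are out of scope; the
  residual step is isotropic ordinary kriging only.
* The RF family cannot extrapolate beyond the training response range;
  at sites unlike every training site (the background site is the
  canonical case) it reverts toward the training mean.
* LOOCV with 35 sites has high variance; single-digit differences in
  R²_mse between families should be read with that in mind.
* The stepwise SLR path is greedy; it reproduces the documented
  procedure, not a best-subset search.
* Variogram fitting on ~34 residuals is noisy by nature; the multistart
  WLS fit is robust, but the fitted range on a single fold is not a
  precise estimate and is not interpreted as one.
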