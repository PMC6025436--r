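# esfr — eigenvector spatial filtering regression for exposure mapping

`esfr` estimates ground-level exposure fields (the motivating case is PM2.5
concentration in µg/m³) from an irregular network of monitoring stations
plus gridded covariates, using **eigenvector spatial filtering regression
(ESFR)**. It is aimed at environmental-epidemiology and air-quality
modellers who have station measurements, raster covariates (AOD,
meteorology, terrain, vegetation, source densities) and need a continuous
concentration map with honest spatial diagnostics.

## The model

Station measurements regressed on covariates alone (GMLR — global multiple
linear regression) leave spatially autocorrelated residuals. ESFR augments
the design with synthetic spatial covariates:

    Y = Xβ + Eα + ε

where `E` holds selected eigenvectors of the doubly centered spatial
weights matrix

    C1 = (I − 11ᵀ/n) C0 (I − 11ᵀ/n),   C0[i,j] = exp(−d_ij / r),

`d_ij` the Euclidean distance between stations and `r` the longest edge of
the minimum spanning tree over the network. Eigenvectors of `C1` are map
patterns ordered by spatial autocorrelation (Moran coefficient
`(n/S0)·λ`); candidates with `λ/λ1 ≥ 0.10` enter a forward stepwise
selection on adjusted R² with all covariates forced in, then insignificant
covariates (p > 0.10) are pruned and selection re-run once. The fitted
combination `Eα` is the *spatial filter* — a map of the model's spatial
component. Out-of-sample prediction (leave-one-out CV, map production)
extends each eigenvector to new locations by the Nyström projection of the
double-centered kernel row.

## Worked example

Everything is testable offline through the seeded synthetic generator,
which states a world mimicking the motivating study (233 stations in a
600 × 500 km region, nine covariate fields with realistic moments, a
3-eigenvector spatial filter, residual σ = 6.8 µg/m³):

```r
library(esfr)
scene <- simulate_scene(sim_config(seed = 7), rasters = FALSE)
model <- fit_esfr(scene$stations)
gmlr  <- fit_gmlr(scene$stations$value, scene$stations$covariates)
model
#> ESFR model: n = 233, p = 19 (8 covariates + 11 eigenvectors)
#>   adj R2 = 0.684, RSE = 6.327, MAPE = 10.28, AICc = 1546.4
#>   pruned covariates:  NDVI
gmlr
#> GMLR model: n = 233, p = 9 (9 covariates + 0 eigenvectors)
#>   adj R2 = 0.510, RSE = 7.883, MAPE = 12.84, AICc = 1636.4

w <- attr(model, "weights")
residual_moran(gmlr, w)
#> Moran's I = 0.2103 (E[I] = -0.0043, z = 17.739, one-sided p = 1.042e-70, normal)
residual_moran(model, w)
#> Moran's I = -0.0383 (E[I] = -0.0043, z = -2.806, one-sided p = 0.9975, normal)
```

Reading the numbers: the baseline's residuals are strongly clustered
(Moran's I = 0.21, p ≈ 1e−70 against the null expectation −1/(n−1)), while
the spatially filtered model leaves slightly dispersed, insignificant
residuals (I = −0.04, one-sided p ≈ 1) — the filter has absorbed the
spatial structure, and adjusted R² rises from 0.51 to 0.68 while RSE drops
from 7.9 to 6.3 µg/m³. Standardized coefficients recover the generating
effects (e.g. pressure +0.61, boundary-layer height −0.48):

```r
round(model$beta, 2)
#>     AOD      ST      PS      RH    PBLH     DEM FactDen RoadDen
#>    0.12   -0.29    0.61    0.21   -0.48   -0.25    0.20    0.14
exceedance_summary(scene$stations$value)   # mean vs the 35 ug/m3 standard
#> [1] 46.8
```

`run_fit(run_config(stations = ...))` wraps the whole procedure and emits
the report tables (coefficients with "/" for pruned covariates, GMLR-vs-ESFR
metric comparison with percent changes, residual Moran's I);
`loocv()` cross-validates either model; `predict_map()` produces the
concentration map, the `Eα` filter surface, and standard-relative level
percentages; `ordinary_kriging()`, `bilinear_resample()`, `point_density()`
and `line_density()` cover covariate preprocessing. A command-line front
end is available via `esfr_cli()` (subcommands `simulate`, `fit`, `cv`,
`diagnose`, `predict-map`, `sources`).

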