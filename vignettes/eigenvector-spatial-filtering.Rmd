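---
title: "Eigenvector spatial filtering regression for exposure mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvector spatial filtering regression for exposure mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esfr)
```

## The problem

Ground monitoring networks for air pollutants such as PM2.5 are sparse and
irregular, while the covariates that explain concentrations — aerosol
optical depth (AOD), meteorology, terrain, vegetation, emission-source
densities — are available as continuous raster grids. A plain multiple
linear regression of station concentrations on those covariates (here
called GMLR, global multiple linear regression) leaves spatially
autocorrelated residuals: nearby stations err in the same direction, the
usual OLS inference is too confident, and maps predicted from the model
miss the spatially clustered part of the signal.

Eigenvector spatial filtering (ESF) addresses this by *constructing*
synthetic spatial covariates. The fitted model is

$$ Y = X\beta + E\alpha + \varepsilon, $$

where $E$ holds $k$ selected eigenvectors of a doubly centered spatial
weights matrix and $E\alpha$ — the *spatial filter* — absorbs the spatially
structured part of the residual. Because the eigenvectors are mutually
orthogonal map patterns with known Moran coefficients, the model remains an
OLS problem.

## Spatial weights and the eigenvector pool

Weights are distance-based: $c_{ij} = \exp(-d_{ij}/r)$ with $d_{ij}$ the
Euclidean distance between stations (the package requires planar
coordinates; `project_equidistant()` is provided for longitude/latitude
input) and $r$ the longest edge of the minimum spanning tree over the
stations — the smallest distance at which the network is still connected,
so no station decouples from the kernel. Centering on both sides with
$M = I - \mathbf{1}\mathbf{1}^\top/n$,

$$ C_1 = M C_0 M, $$

gives the operator whose eigenvectors are the candidate patterns. For any
eigenvector $e_j$ of $C_1$ the Moran coefficient is exactly
$(n/S_0)\,\lambda_j$ with $S_0$ the total weight, so ordering by eigenvalue
orders by spatial autocorrelation; candidates are screened by
$\lambda_j/\lambda_1 \ge 0.10$ (boundary inclusive, configurable).

Two conventions the weights construction had to pin down:

* **Kernel diagonal.** The kernel itself gives $\exp(0) = 1$ on the
  diagonal. The package zeroes it by default (self-influence excluded, the
  usual Moran-operator convention) and exposes `diagonal = "one"` because
  either choice is defensible; the two spectra differ only by a constant
  pattern shift.
* **Coincident stations** are rejected with an error, never jittered:
  silent jitter would change $r$ and the whole eigenbasis irreproducibly.

Eigenvector signs from LAPACK are arbitrary, so each column is normalized
to have its largest-magnitude entry positive; ties take the first such
entry. With exactly repeated eigenvalues the basis is inherently
non-unique; the package keeps the solver's ordering stably and documents
the caveat rather than pretending uniqueness.

## Estimation procedure

`fit_esfr()` runs the five steps in order: (1) weights, (2)
eigendecomposition and candidate screening, (3) forward stepwise selection
of eigenvectors with all covariates forced in, (4) OLS, (5) pruning of
covariates with two-sided $p > 0.10$ followed by one repetition of steps
(3)–(4) on the reduced set (not iterated to convergence).

The stepwise criterion deserves a note. Plain $R^2$ never decreases under
nesting, so it cannot define a stopping rule; the package uses adjusted
$R^2$: at each round the candidate with the largest adjusted-$R^2$ gain is
added, and selection stops when no candidate improves it. Greedy selection
over a pool of $m$ candidates picks maxima of chance correlations, so on
data with *no* spatial signal a handful of eigenvectors (and a modest
adjusted-$R^2$ inflation of up to several hundredths) can still enter; this
is a property of the stated rule, not a defect of the implementation, and
the test suite asserts it at that realistic magnitude. No significance
filter is applied to the eigenvector coefficients themselves — selection
relies solely on adjusted-$R^2$ improvement.

All variables (response, covariates, eigenvectors) are z-scored before
fitting, so reported coefficients are standardized "Beta" values; the
stored (mean, sd) pairs make raw-scale predictions exact. Error metrics are
reported on the raw scale: RSE $=\sqrt{RSS/(n-p-1)}$ in response units,
MAPE in percent (flagged undefined when an observation is exactly zero
rather than returning infinity), and AICc with Gaussian ML likelihood and
$k = p + 2$ parameters (intercept and variance counted) — AICc conventions
differ enough that this is stated explicitly.

## Diagnostics

`global_moran()` implements Moran's I with the analytic normal
approximation under the randomization assumption and a one-sided upper-tail
p-value (alternative: positive autocorrelation), so a negative I yields p
near 1 — matching the convention in which insignificant filtered residuals
print p-values like 0.97. A permutation test is available behind a flag.
The weights for Moran's I default to the same exponential kernel (zero
diagonal, unstandardized) used for the eigenbasis, so the observation-level
and residual-level statistics share one spatial structure;
row-standardization is available. Residual Moran's I uses the raw statistic
on OLS residuals, without a residual-specific variance correction — a
documented simplification.

## Out-of-sample eigenvectors and LOOCV

Eigenvectors live on the training stations; predicting elsewhere needs
their values at new locations. The package uses the Nyström extension: the
kernel row $c$ from the new site to the training stations is double
centered against the training kernel,
$\tilde c_i = c_i - \overline{c} - \overline{c_{\cdot i}} + \overline{C_0}$,
and projected, $\tilde e_j(s_0) = \tilde c^\top e_j / \lambda_j$ (defined
only for $\lambda_j > 0$). At a training station this reproduces the stored
eigenvector entry exactly, which is why mapped predictions agree with
fitted values in-sample. This kernel-projection extension is the package's
reading of "interpolation minimizing expected error"; a published
estimator's exact internals were not reverse-engineered, and this is the
main methodological approximation of the cross-validation module.

`loocv()` re-runs the *entire* chain per fold — distances, MST range,
kernel, centering, eigendecomposition, screening, stepwise, OLS, pruning —
on the $n-1$ training stations (the stricter reading of the procedure; no
attempt is made to align fold-wise eigenvectors with full-data ones), then
predicts the held-out station via the extension. Folds with rank-deficient
designs are flagged and excluded from the MSE with a reported count.

## Gridding and maps

* **Ordinary kriging** (for coarse meteorology) solves the semivariance
  system with the unbiasedness constraint per target cell; the spherical
  variogram is fitted to a 12-bin empirical semivariogram (bins to half the
  maximum distance) by pair-count-weighted least squares, since the
  original procedure names the model but not the fit. With a flat (pure
  nugget) variogram the decomposition nugget-vs-range is not identifiable —
  only the sill is — and the tests assert exactly that stable part.
* **Bilinear resampling** (for finer-grid covariates) interpolates among
  the four surrounding source cell centers; any nodata corner propagates.
* **Raster convention**: origin at the upper-left corner, row-major, cell
  centers at half-cell offsets, equal cell areas. Rasters are exchanged as
  ESRI ASCII grids (plain text); GeoTIFF support would need a raster
  dependency not available in the target environment.
* **Exposure maps** (`predict_map()`) evaluate the model at every valid
  cell, extending selected eigenvectors by Nyström at cell centers
  (kriging the eigenvector surfaces is a conceivable alternative; the
  extension is used because it is the same operator LOOCV uses).
  Predictions are back-transformed to concentration units; the filter
  surface $E_k\beta_k$ is left on the standardized-response scale so maps
  are comparable across periods. Cells are classified against a standard
  (default 35 ug/m3) into four levels with boundaries belonging to the
  lower level, and area percentages are computed over valid cells. The map
  mean and the station mean are both reported, because eigenvector
  extension decays away from the network and can pull the map mean below
  the observed mean.

Source-density surfaces count points (or clip polyline lengths,
analytically) within a 24-km disk centered on each cell center, normalize
by the disk area, min-max normalize each layer to $[0,1]$, and average the
two layers. Whether the original densities were area-normalized is
unknowable from the text; after min-max normalization the composite is
invariant to that choice. Exact-coordinate duplicate points are removed
before counting.

## The synthetic world

Real station/satellite data are not packaged. The generator
(`sim_config()`, `simulate_scene()`) states a world once and the tests
measure the method against it:

* 233 stations uniform over a 600 km x 500 km region with a
  minimum-separation rejection rule (0.1% of the region diagonal).
* Nine covariates as independent low-order cosine random fields whose
  means and s.d.s take the published annual summary magnitudes (e.g. ST
  292.0 K, PS 1001.3 hPa, PBLH 389.7 m); integer-frequency modes make the
  continuum moments exact, so the affine map to target moments does not
  depend on where the field is evaluated. Rasters default to 3-km cells.
* Standardized covariate effects take the published annual-model values
  (PS 0.68, PBLH −0.66, ST −0.46, ...; road density 0), converted to raw
  scale through the published response s.d. (7.9) around a mean of 51.3.
* A spatial filter on the first three eigenvectors with raw-scale
  coefficients (60, −45, 35), i.e. filter variance
  $\sum\alpha_k^2/n \approx 29$ at $n = 233$.
* Residual s.d. $\sigma = 6.8$, chosen once so that the population
  adjusted $R^2$ is about 0.70, the headline annual fit of the motivating
  study.

The filter is generated from the same eigenbasis the pipeline recomputes
(a well-specified regime — parameter-recovery tests need one); covariate
fields are mutually independent, unlike the correlated real covariates. A
green test therefore establishes that the machinery recovers a truth of
this structure — not that the real data satisfy it, and not the published
headline numbers themselves, which would require the original datasets.

## Numerical and testing notes

* Centering/symmetry tolerances scale as $10^{-9} n$; eigen-identities are
  asserted at $10^{-8}$.
* The constant vector is in the null space of $C_1$; its "eigenvector" has
  zero variance and is excluded wherever a Moran quantity is computed.
* Stepwise uses incremental orthogonalization (each candidate evaluation is
  $O(n)$), which is what makes per-fold re-selection inside LOOCV
  affordable.
* The acceptance-style LOOCV comparison (ESFR vs GMLR prediction error on
  filter-bearing data, 25 replicates) runs at $n = 120$ rather than 233:
  the direction of the comparison is scale-free and the smaller network
  keeps 25 x 2 full leave-one-out runs inside the test budget.
* The type-I error of the Moran test is checked empirically (2000 null
  replicates at $n = 100$) against the nominal 0.05 level.

## Limitations

Negative-autocorrelation filters (selection among negative eigenvalues) are
out of scope, as are contiguity-based weights, sparse eigensolvers for
$n \gg 10^3$, LASSO-based selection, spatial autoregressive alternatives,
geographically weighted or spatio-temporal extensions, and any satellite
retrieval/QC preprocessing. MAPE assumes strictly positive observations.
The LOOCV eigenvector extension is a kernel-projection approximation, and
repeated eigenvalues make the selected basis non-unique in degenerate
geometries.
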