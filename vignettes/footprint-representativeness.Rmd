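---
title: "Footprint climatologies and flux-tower representativeness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint climatologies and flux-tower representativeness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxrep)
```

This vignette documents the models, parameter choices and numerical
decisions behind `fluxrep`, and what the synthetic test conditions do and
do not establish about real tower data.

## The footprint model and its drivers

The half-hourly footprint `f(x, y)` is the weight with which each surface
location contributes to the turbulent flux measured at the sensor: the
measured flux is the integral of the surface source field times `f` over
the upwind domain, so `f` integrates to one over an unbounded domain. We
use the widely-adopted two-dimensional parameterization in which the
crosswind-integrated footprint is a power-law-times-exponential curve in a
scaled upwind distance,

    F*(X*) = a (X* - d)^b exp(-c / (X* - d)),

with the published fitted constants `a = 1.4524`, `b = -1.9914`,
`c = 1.4622`, `d = 0.1359` taken verbatim from the parameterization's
source publication (re-fitting them is not this package's business). The
scaling from `X*` to metres involves the measurement height above the
zero-plane displacement `zm - d`, the log-profile factor
`log((zm - d)/z0) - psi` with the usual integrated stability correction
`psi(L)`, and the boundary-layer depth factor `1 - (zm - d)/pblh`.
Crosswind, the plume is Gaussian with the parameterized spread
`sigma_y*(X*) = 2.17 sqrt(1.66 X*^2 / (1 + 20 X*))`, rescaled by
`zm - d`, `sigma_v / ustar` and a stability-dependent constant. The
streamwise axis is rotated so the source area lies toward the
meteorological wind direction (the bearing the wind comes *from*) — the
grid is tower-centred with x east and y north, and a source at upwind
distance `x_s` sits at bearing `wd` from the tower.

Driver derivation follows standard surface-layer practice:

* roughness length `z0 = 0.1 hc` and displacement `d = 0.67 hc` from
  canopy height;
* Obukhov length `L = -rho cp T ustar^3 / (k g H)` from sensible heat
  flux, temperature and pressure (the flux tables carry `H`, `TA`, `PA`
  but not `L`, and no authoritative recipe exists in the data source, so
  the standard formula is assumed);
* boundary-layer height: measured values pass through; under stable or
  neutral stratification the Nieuwstadt equilibrium height
  `h = L/3.8 (-1 + sqrt(1 + 2.28 ustar / (f L)))` with the Coriolis
  parameter at the site latitude; under convective conditions no
  equilibrium diagnostic exists without time integration, so a
  configurable default (2000 m) is used. Within 5 degrees of the equator
  the Coriolis parameter is too small and the default applies everywhere.

Records must satisfy the parameterization's validity bounds
(`zm/L >= -15.5`, `20 z0 < zm < 0.8 pblh`). A record failing several rules
is counted under the first failed rule in the order stability, lower
height, upper height — an arbitrary but deterministic attribution.

**Fetch convention.** The curve `F*` has a heavy power-law tail
(`b` is close to -2), so its cumulative converges extremely slowly: no
finite grid captures "all" of the footprint. Percentile distances of the
1-D profile (`footprint_extent()`) therefore follow the reference
convention of evaluating the curve to `X* = 30` and normalizing the
cumulative over that span. Climatology-level contours are instead defined
on the normalized accumulated grid, where the domain itself is the
universe.

## The lateral-wind-speed predictor

Many towers lack the lateral wind speed standard deviation σ_v that the
crosswind model needs. Following the approach of training an ensemble
regressor on towers that do report it, `fit_sigma_v()` fits a random
forest (ranger, 100 trees, `mtry = 5` — with only seven smooth covariates
the square-root default of 2 underfits) on USTAR, WS, SW_IN, PA, z0, Hm
and Hc, and reports pooled k-fold cross-validated R² and MAE. Predictions
only ever fill missing values; measured σ_v is never overwritten.

The synthetic training generator draws the covariates over realistic
ranges and computes σ_v from a documented smooth function (dominated by
`1.1 USTAR + 0.10 USTAR·WS`, with weak contributions from the other
drivers) plus Gaussian noise. Because the generating function is known,
the best attainable R² of *any* predictor is
`var(signal) / (var(signal) + noise_sd^2)`; by default the noise is
calibrated so this ceiling is 0.78, and the test suite checks that the
cross-validated forest lands within 0.05 of the ceiling. This verifies
the estimation machinery, not the realism of the covariate-σ_v relation
at real towers.

## Climatology, contours and geometry

Accepted footprints are summed cell-wise and renormalized
(`accumulate_footprints()`); monthly or seasonal climatologies are the
same operation on time slices, and only the annual climatology feeds the
downstream stages. The r% contour is defined on cells: the smallest set
of highest-weight cells whose summed weight reaches r/100, with ties
broken by weight, then row, then column. This makes the sets nested
across levels, scale-invariant, and exactly testable — a 2-D isotropic
Gaussian climatology with scale σ must give area
`-2 pi sigma^2 log(1 - r/100)`, and the suite requires agreement within
3% at cell ≤ σ/10. The marching-squares boundary polyline is cosmetic
(plots, CSV export); area, fetch and symmetry index come from the cell
set. Fetch is the maximum distance from the tower to a boundary *cell
centre*, which underestimates the geometric boundary by up to half a
cell — visible in the symmetry-index tests, whose tolerance (2–3%)
is the grid tolerance at the test resolution.

## Land cover

The 30 m fine-classification codes recode one-for-one onto IGBP classes
per the published aggregation table (including its nonstandard numbering:
water bodies 18, unclassified 17). Cover percentages are footprint-
weighted: each climatology cell inside the 80% contour samples the
nearest land-cover cell (the co-registration rule everywhere in the
package is nearest-neighbour sampling at cell centres; no published
resampling rule exists to follow). Savanna, woody-savanna and
closed-shrubland sites have no counterpart class in the product; the
dominant aggregated type at such sites is accepted through a fixed alias
table (WSA→DBF, SAV→ENF, CSH→DBF). Mismatching sites are flagged, never
dropped — dropping is a reporting choice, not a computation.

## Heterogeneity: semivariograms

Inside the 80% contour the NDVI semivariogram is estimated in four 45°
sectors (E-W, NE-SW, N-S, NW-SE; ±22.5° tolerance so the sectors tile the
plane) and averaged per lag to an omnidirectional curve. Lag bins are one
NDVI cell (10 m); the default maximum lag is half the diagonal of the
mask's bounding box. Two estimators are provided, because the published
wording ("weighted NDVI values") is ambiguous: the default weights each
pair by the product of the footprint weights at its two pixels,
normalized per lag; the unweighted mode is exactly the classical half
mean squared difference and is oracle-checked against a brute-force
all-pairs enumeration to 1e-12.

The spherical model
`gamma(h) = nugget + (sill - nugget)(1.5 h/a - 0.5 (h/a)^3)` for `h < a`
is fitted by bounded weighted least squares (L-BFGS-B plus a
derivative-free polish), with constraints `0 <= nugget <= sill`, `a > 0`.
Numerical choices worth knowing:

* **Fit weights** are the per-lag effective pair weights, which reduce to
  the pair counts `N(h)` for the unweighted estimator. For the
  footprint-weighted estimator, raw pair counts would let the longest
  lags — many pixel pairs but almost no footprint weight, hence noisy
  γ̂ — dominate the objective and push the fit into boundary minima;
  weighting by the information the estimator actually used is the
  consistent choice.
* **The range is capped at 1.5× the maximum lag**: beyond the observed
  window it is not identifiable, and an uncapped fit responds to tail
  noise by extrapolating an arbitrary sill.
* Initialization: nugget from the first lag, sill from the mean of the
  last third of lags, range from the first lag reaching 95% of that
  sill. A flat variogram collapses to the pure-nugget model
  (nugget = sill, ratio 100%, range at its lower bound) with a warning.

On a simulated field with truth (nugget 2e-4, sill 1e-3, range 240 m) the
full-field estimator recovers the range within a few percent; inside an
irregular footprint mask the weighted estimate is noisier, and the suite
requires ±20% on the range, ±25% on the sill.

## Sensor location bias and classification

`SLB = (NDVI_fp - NDVI_target) / NDVI_target` with
`NDVI_fp = sum(phi_j NDVI_j)` over the 80% mask (weights renormalized to
one) — a relative quantity, invariant to rescaling both inputs and
undefined at a zero target mean (flagged, returned `NA`). The
contour-target mean is the *unweighted* mean NDVI inside the 80% mask.
Window targets are tower-centred squares of side `30(2i-1)` m,
`i = 1..50` (30 m to 2970 m); membership is by cell-centre test, which is
deterministic and resolution-stable. Windows reaching beyond the raster
are truncated with a warning.

Classification bands (level 1 High / 2 Medium / 3 Low): dominant cover
percentage <50 → 3, 50–80 → 2, >80 → 1; nugget/sill ratio <25 → 1,
25–75 → 2, >75 → 3; |SLB| <0.05 → 1, 0.05–0.1 → 2, >0.1 → 3. The
published band notation leaves the endpoints ambiguous; here every
boundary value belongs to the middle band, so the maps are monotone and
total.

## The synthetic scene: what it emulates, and what it does not

`scene_config()` fixes a seed and the study conditions; each generator is
a pure function of the config, with per-stage sub-seeds so generators can
be called in any order.

* **Met series** — wind directions from a mixture rose (default: a
  two-lobed SW/NE rose, 65/35, 25° spread), wind speed lognormal (median
  ≈ 3 m s⁻¹), friction velocity proportional to wind speed with noise,
  and a stability mix (default 50% unstable / 20% neutral / 30% stable)
  realized through the sensible heat flux, so the Obukhov length derived
  from `H`, `TA`, `PA` has the right sign and magnitude by construction.
  The defaults are a plausible mid-latitude site; they are conditions,
  not tuning knobs.
* **Land cover** — deterministic painted geometry (background fill plus
  discs, rectangles, half-planes) in fine-classification codes. The
  default scene is needleleaf forest with a grass disc 640 m to the
  north-east and a cropland band to the south.
* **NDVI** — a Gaussian random field with spherical covariance simulated
  by FFT circulant embedding on the torus (wrap-around correlation is
  negligible while range ≪ domain; small negative embedding eigenvalues
  are clamped to zero), plus independent cell noise for the nugget, around
  a mean of 0.45, clipped to [-1, 1]. Default truth: nugget 2e-4, sill
  1e-3, range 240 m — magnitudes typical of an annual composite over a
  moderately heterogeneous site. `sill = 0` yields a constant field.
* **Tower** — 40 m measurement height over an 18 m canopy, IGBP
  needleleaf forest, at 56° N.

The domain half-width default is 2100 m: both the 30 m land-cover and
10 m NDVI cells divide it exactly, and it approximates the ±0.02°
clipping window used for such analyses.

What passing tests on these scenes establishes: the footprint numerics
match the parameterization's closed forms; the contour, overlay,
variogram and bias estimators compute exactly what their definitions say;
and the estimation chain recovers known ground truth within stated
tolerances. What they do not establish: realism of the generators with
respect to any particular ecosystem — real towers have diurnal and
seasonal structure, correlated gaps, NDVI trends and anisotropy, land
cover misclassification, and terrain effects, none of which are emulated.
Results on real data inherit those caveats.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by choice:
pipeline smoke runs use 120–2000 half-hours on 20–30 m grids, variogram
recovery uses one 420 × 420 field at 10 m, and the σ_v model trains on
6000 rows. All randomness flows from a single integer seed; two runs of
`run_pipeline()` with the same config write byte-identical tables.

## Known limitations

* The source-area percentile of a single half-hourly footprint depends on
  the truncation convention (see the fetch note above); only climatology-
  level contours are convention-free within the domain.
* The weighted variogram under a small or elongated mask is noisy at long
  lags; the nugget/sill ratio is stable, the range less so.
* No blending of alternative footprint models is attempted, no
  along-wind advection correction, and no multi-year climatology —
  single-year annual analysis only.
* ASCII-grid raster output carries tower-relative metric coordinates, not
  a geographic projection.
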