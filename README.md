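# fluxrep

Spatial representativeness of eddy-covariance flux towers.

An eddy-covariance (EC) tower measures the net exchange of CO2, water and
energy over a *footprint* — the upwind surface area that actually
contributes to the signal at the sensor, which shifts with wind direction
and atmospheric stability every half hour. Users who pair tower fluxes with
satellite pixels, model grid cells or plant-functional-type labels
implicitly assume the footprint looks like the target area. `fluxrep`
quantifies how good that assumption is for a given site, and classifies the
site's representativeness on three axes.

The pipeline:

1. **Footprint model** — the two-dimensional flux footprint
   parameterization driven by half-hourly wind speed, wind direction,
   friction velocity u\*, lateral wind spread σ_v, Obukhov length L and
   boundary-layer height. The crosswind-integrated density is the published
   power-law × exponential curve in scaled upwind distance
   F\*(X\*) = a (X\*−d)^b exp(−c/(X\*−d)); the crosswind spread is Gaussian
   with a parameterized σ_y(x). Records outside the validity bounds
   (z_m/L ≥ −15.5 and 20 z_0 < z_m < 0.8 pblh) are filtered out.
2. **Footprint climatology** — accepted half-hourly footprints are
   accumulated and normalized into the annual cumulative footprint
   climatology (ACFC); 50/60/70/80 % source-area contours are extracted as
   cell-set quantiles, with area, fetch (maximum tower-to-contour
   distance) and the symmetry index SI = A/(π·fetch²).
3. **Land cover** — a 30 m fine-classification raster is recoded to IGBP
   classes and overlaid with the 80 % contour to give footprint-weighted
   cover percentages and the dominant type.
4. **Heterogeneity** — directional semivariograms
   γ̂(h) = Σ w (z(x)−z(x+h))² / (2 Σ w) of NDVI inside the 80 % contour in
   four 45° sectors, averaged to an omnidirectional estimate and fitted
   with a spherical model (nugget, sill, range).
5. **Sensor location bias** — SLB = (NDVI_fp − NDVI_target)/NDVI_target,
   with NDVI_fp = Σ φ_j·NDVI_j the footprint-weighted NDVI, against the
   80 % contour and against tower-centred square windows of side
   l_i = 30·(2i−1) m, i = 1…50.
6. **Classification** — three indicator levels (1 High / 2 Medium / 3 Low)
   from the dominant-cover percentage, the nugget-to-sill ratio and |SLB|.

Because the real inputs (tower networks, 30 m land-cover products, Landsat
NDVI) need registration to download, the package ships a **synthetic scene
generator**: half-hourly met series with a configurable wind rose and
stability mix, patchy categorical land-cover rasters, NDVI fields simulated
as Gaussian random fields with a prescribed spherical variogram, and
training data for the σ_v random-forest predictor with an analytically
known attainable R². Every stage of the pipeline is exercised and tested
against these controlled inputs.

## Worked example

```r
library(fluxrep)

cfg <- scene_config(seed = 42, n_halfhours = 1000)
run <- run_pipeline(cfg, verbose = FALSE)
run
#> <fluxrep_run> site SYN-001, 937 half-hours accumulated
#>   dominant cover: ENF 97.9% (match: TRUE)
#>   omnidirectional nugget/sill: 36.4%
#>   |SLB| vs 80% contour: 0.0029
#>   classification (Rp, Rs, Rb): 1, 2, 1

run$contours$summary
#> # A tibble: 4 × 6
#>   level n_cells area_m2 area_km2 fetch_m    si
#>   <dbl>   <int>   <dbl>    <dbl>   <dbl> <dbl>
#> 1    50     994   99400   0.0994    243. 0.536
#> 2    60    1712  171200   0.171     326. 0.513
#> 3    70    3153  315300   0.315     455. 0.484
#> 4    80    6643  664300   0.664     682. 0.455

run$cover
#> # A tibble: 2 × 4
#>   igbp_code abbrev igbp_name                     pct
#>       <int> <chr>  <chr>                       <dbl>
#> 1         1 ENF    Evergreen Needleleaf Forest 97.9
#> 2        10 GRA    Grasslands                   2.15

glance(run$spherical_fit)
#> # A tibble: 1 × 7
#>     nugget     sill range_m nugget_sill_ratio     sse converged n_lags
#>      <dbl>    <dbl>   <dbl>             <dbl>   <dbl> <lgl>      <int>
#> 1 0.000295 0.000809    221.              36.4 0.00120 TRUE          72
```

Reading the output: of 1000 generated half-hours, 937 passed the validity
filter and were accumulated. The 80 % source area covers 0.66 km² with a
682 m fetch; its symmetry index 0.46 reflects the two-lobed wind rose. The
footprint sees 97.9 % evergreen needleleaf forest, matching the site label
(Rp = 1). The NDVI field was simulated with a 240 m spherical range; the
footprint-weighted variogram recovers 221 m, and its nugget/sill ratio of
36 % lands the site in the medium heterogeneity band (Rs = 2). The
footprint-weighted NDVI differs from the 80 %-contour mean by 0.3 %
(|SLB| = 0.0029 < 0.05, Rb = 1).

Plot helpers: `autoplot(run$acfc, run$contours)` draws the climatology with
its contours, `autoplot(run$omni, fit = run$spherical_fit)` the variogram,
`autoplot(run$windows)` the window-size bias profile. `tidy()`/`glance()`
methods cover the fitted objects. `run_pipeline(..., out_dir = "out")`
writes all stage tables as CSV (contours in the `fp50_x`/`fp50_y` dialect)
plus ASCII-grid rasters and a run manifest.

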