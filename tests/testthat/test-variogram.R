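test_that("ndvi band arithmetic and masking follow the normalized difference", {
  nir <- flux_raster(matrix(c(0.5, 0.3, 0, 0.2), 2, 2), 10)
  red <- flux_raster(matrix(c(0.1, 0.3, 0, 0.1), 2, 2), 10)
  ndvi <- compute_ndvi(nir, red)
  expect_equal(ndvi$values[1, 1], 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(ndvi$values[2, 1], 0)          # equal bands
  expect_true(is.na(ndvi$values[1, 2]))       # zero band sum masked
  expect_error(compute_ndvi(nir, flux_raster(matrix(0.1, 3, 3), 10)),
               "co-registered")
  # bands built from a known field invert exactly
  f <- flux_raster(matrix(runif(16, -0.5, 0.9), 4, 4), 10)
  b <- ndvi_to_bands(f)
  expect_equal(compute_ndvi(b$nir, b$red)$values, f$values,
               tolerance = 1e-12)
})

test_that("annual composite drops cloudy scenes with a strict 5% filter", {
  r1 <- flux_raster(matrix(0.2, 3, 3), 10)
  r2 <- flux_raster(matrix(0.4, 3, 3), 10)
  out <- annual_composite(list(r1, r2), c(1, 4.9))
  expect_equal(out$values, matrix(0.3, 3, 3))
  # a scene at exactly 5.0% is dropped
  out2 <- annual_composite(list(r1, r2), c(1, 5.0))
  expect_equal(out2$values, matrix(0.2, 3, 3))
  expect_equal(annual_composite(list(r1), 0)$values, r1$values)
  expect_error(annual_composite(list(r1, r2), c(5, 80)), "all scenes")
})

test_that("semivariogram reproduces hand-enumerated values", {
  # constant field: zero everywhere
  const <- fluxrep:::empirical_variogram_matrix(matrix(5, 6, 6), cell = 1)
  expect_true(all(const$gamma == 0))

  # 1-D transect 0,1,0,1 at lag 1: three pairs, each squared diff 1
  tr <- fluxrep:::empirical_variogram_matrix(
    matrix(c(0, 1, 0, 1), 1, 4), cell = 1, direction = "EW", max_lag = 1
  )
  expect_equal(tr$gamma, 0.5)
  expect_equal(tr$n_pairs, 3)
})

test_that("optimized estimator equals the naive all-pairs oracle", {
  withr::with_seed(77, {
    z <- matrix(rnorm(25), 5, 5)
    w <- matrix(rexp(25), 5, 5)
    mask <- matrix(runif(25) > 0.2, 5, 5)
    for (dir in c("omni", "EW", "NS", "NE-SW", "NW-SE")) {
      fast_u <- fluxrep:::empirical_variogram_matrix(
        z, mask = mask, cell = 1, direction = dir
      )
      slow_u <- naive_variogram(z, mask = mask, cell = 1, direction = dir)
      expect_equal(fast_u$gamma, slow_u$gamma, tolerance = 1e-12)
      expect_equal(fast_u$n_pairs, slow_u$n_pairs)
      fast_w <- fluxrep:::empirical_variogram_matrix(
        z, mask = mask, weights = w, cell = 1, direction = dir,
        weighted = TRUE
      )
      slow_w <- naive_variogram(z, mask = mask, weights = w, cell = 1,
                                direction = dir, weighted = TRUE)
      expect_equal(fast_w$gamma, slow_w$gamma, tolerance = 1e-12)
    }
  })
})

test_that("semivariance ignores level shifts and scales quadratically", {
  withr::with_seed(12, {
    z <- matrix(rnorm(100), 10, 10)
    base <- fluxrep:::empirical_variogram_matrix(z, cell = 1)
    shifted <- fluxrep:::empirical_variogram_matrix(z + 3.7, cell = 1)
    scaled <- fluxrep:::empirical_variogram_matrix(z * 2.5, cell = 1)
    expect_equal(shifted$gamma, base$gamma, tolerance = 1e-12)
    expect_equal(scaled$gamma, 2.5^2 * base$gamma, tolerance = 1e-12)
  })
})

test_that("omnidirectional estimate is the per-lag mean of the directions", {
  mk <- function(g) {
    out <- tibble::tibble(direction = "EW", h = c(10, 20), gamma = g,
                          n_pairs = c(5, 5), sum_w = c(5, 5))
    class(out) <- c("variogram_estimate", class(out))
    out
  }
  four <- list(mk(c(1, 1)), mk(c(2, 2)), mk(c(3, 3)), mk(c(4, 4)))
  omni <- omnidirectional_semivariogram(four)
  expect_equal(omni$gamma, c(2.5, 2.5))
  expect_equal(omni$n_pairs, c(20, 20))
  same <- omnidirectional_semivariogram(rep(list(mk(c(1, 2))), 4))
  expect_equal(same$gamma, c(1, 2))
  # disjoint lag grids cannot be averaged
  shifted <- mk(c(1, 1))
  shifted$h <- c(30, 40)
  expect_error(omnidirectional_semivariogram(list(mk(c(1, 1)), shifted)),
               "common lags")
})

test_that("spherical fit recovers exact curves and degrades gracefully", {
  h <- seq(10, 600, by = 10)
  curve <- fluxrep:::spherical_curve(h, 2e-4, 1e-3, 240)
  vgm <- tibble::tibble(direction = "omni", h = h, gamma = curve,
                        n_pairs = rep(100, length(h)),
                        sum_w = rep(100, length(h)))
  fit <- fit_spherical(vgm)
  expect_equal(fit$nugget, 2e-4, tolerance = 1e-6)
  expect_equal(fit$sill, 1e-3, tolerance = 1e-6)
  expect_equal(fit$range_m, 240, tolerance = 1e-6)
  expect_equal(fit$nugget_sill_ratio, 20, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(tidy(fit)$estimate, c(fit$nugget, fit$sill, fit$range_m))
  expect_equal(glance(fit)$range_m, fit$range_m)

  # flat variogram: pure nugget, ratio 100%, flagged
  flat <- vgm
  flat$gamma <- rep(6e-4, length(h))
  expect_warning(ffit <- fit_spherical(flat), "flat|degenerate")
  expect_equal(ffit$nugget, ffit$sill, tolerance = 1e-6)
  expect_equal(ffit$nugget_sill_ratio, 100, tolerance = 0.1)

  expect_error(fit_spherical(vgm[1:3, ]), "at least 4")
  # ratio always lands in [0, 100] under the constraints
  withr::with_seed(5, {
    for (k in 1:5) {
      noisy <- vgm
      noisy$gamma <- pmax(curve + rnorm(length(h), 0, 1e-4), 0)
      f <- fit_spherical(noisy)
      expect_gte(f$nugget_sill_ratio, 0)
      expect_lte(f$nugget_sill_ratio, 100)
      expect_lte(f$nugget, f$sill)
    }
  })
})

test_that("masked, weighted variogram runs end to end on a scene", {
  cfg <- small_scene(seed = 8, n_halfhours = 80)
  ndvi <- gen_ndvi_field(cfg)
  met <- gen_met_series(cfg)
  meta <- site_meta("S", 1, 56, 10, zm = cfg$tower$zm, hc = cfg$tower$hc)
  kept <- qc_filter(met, meta)
  kept <- head(kept[!is.na(kept$sigma_v), ], 10)
  grid <- grid_spec(cell = 30, half_width = cfg$half_width)
  fps <- lapply(seq_len(nrow(kept)), function(i) {
    halfhour_footprint(kept[i, ], meta, grid)
  })
  acfc <- accumulate_footprints(fps)
  contours <- extract_contours(acfc)
  vgms <- lapply(c("EW", "NE-SW", "NS", "NW-SE"), function(d) {
    directional_semivariogram(ndvi, acfc, contours, direction = d,
                              max_lag = 300)
  })
  omni <- omnidirectional_semivariogram(vgms)
  expect_true(all(omni$gamma >= 0))
  expect_true(all(omni$n_pairs > 0))
  # weighted and unweighted modes agree in order of magnitude on a GRF
  unw <- directional_semivariogram(ndvi, acfc, contours, direction = "EW",
                                   weighted = FALSE, max_lag = 300)
  expect_true(all(unw$gamma >= 0))
  fit <- fit_spherical(omni)
  expect_gt(fit$range_m, 0)
})
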