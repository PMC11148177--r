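test_that("met generator is seed-deterministic and regime-consistent", {
  cfg <- scene_config(seed = 1, n_halfhours = 1000)
  m1 <- gen_met_series(cfg)
  m2 <- gen_met_series(cfg)
  expect_identical(m1, m2)
  expect_true(all(m1$ws > 0))
  expect_true(all(m1$wd >= 0 & m1$wd < 360))
  expect_true(all(m1$ustar >= 0.05 & m1$ustar <= 1.5))
  expect_true(all(m1$pblh > 0))

  # regime fractions match the configured mix within binomial error
  mix <- cfg$stability_mix
  frac <- table(factor(m1$regime, names(mix))) / nrow(m1)
  se <- sqrt(mix * (1 - mix) / nrow(m1))
  expect_true(all(abs(frac - mix) < 4 * se + 1e-12))

  # L sign follows the regime
  expect_true(all(m1$L[m1$regime == "unstable"] < 0))
  expect_true(all(m1$L[m1$regime == "stable"] > 0))

  cfg_u <- scene_config(seed = 2, n_halfhours = 300,
                        stability_mix = c(unstable = 1, neutral = 0,
                                          stable = 0))
  expect_true(all(gen_met_series(cfg_u)$L < 0))

  expect_error(
    scene_config(stability_mix = c(unstable = 0.6, neutral = 0.6,
                                   stable = -0.2)),
    "stability_mix"
  )
})

test_that("wind rose concentrated at 90 degrees yields circular mean near 90", {
  cfg <- scene_config(
    seed = 4, n_halfhours = 2000,
    wind_rose = data.frame(bearing = 90, prob = 1), wind_rose_sd = 20
  )
  wd <- gen_met_series(cfg)$wd
  delta <- abs(circular_mean(wd) - 90)
  expect_lt(min(delta, 360 - delta), 5)
})

test_that("landcover raster honours patch geometry", {
  cfg1 <- scene_config(landcover_patches = list(list(class = 130)))
  lc1 <- gen_landcover_raster(cfg1)
  expect_true(all(lc1$values == 130))

  # two half-plane patches splitting the domain east/west
  cfg2 <- scene_config(landcover_patches = list(
    list(class = 130),
    list(class = 70, type = "halfplane", bearing = 90, offset = 0)
  ))
  lc2 <- gen_landcover_raster(cfg2)
  frac <- mean(lc2$values == 70)
  n <- ncol(lc2$values)
  expect_lt(abs(frac - 0.5), 1 / n + 1e-9)
  expect_identical(lc2$values, gen_landcover_raster(cfg2)$values)

  expect_error(
    scene_config(landcover_patches = list(list(class = 999))),
    "unknown land-cover class"
  )
})

test_that("ndvi field follows the prescribed spherical covariance", {
  cfg0 <- scene_config(seed = 9,
                       variogram_truth = c(nugget = 0, sill = 0, range_m = 240))
  f0 <- gen_ndvi_field(cfg0)
  expect_equal(stats::sd(as.vector(f0$values)), 0)
  expect_true(all(f0$values == cfg0$ndvi_mean))

  expect_error(
    scene_config(variogram_truth = c(nugget = -1e-4, sill = 1e-3,
                                     range_m = 240)),
    "variogram_truth"
  )

  cfg <- scene_config(seed = 9)  # truth: nugget 2e-4, sill 1e-3, range 240 m
  f <- gen_ndvi_field(cfg)
  expect_identical(f$values, gen_ndvi_field(cfg)$values)
  expect_true(all(f$values >= -1 & f$values <= 1))
  expect_gte(nrow(f$values), 400)

  vt <- cfg$variogram_truth
  expect_lt(abs(var(as.vector(f$values)) - vt[["sill"]]) / vt[["sill"]],
            0.15)

  # empirical semivariances at lags up to the range track the true curve
  vg <- fluxrep:::empirical_variogram_matrix(
    f$values, cell = f$cell, direction = "omni", max_lag = vt[["range_m"]]
  )
  truth <- vt[["nugget"]] +
    (vt[["sill"]] - vt[["nugget"]]) *
      (1.5 * pmin(vg$h / vt[["range_m"]], 1) -
         0.5 * pmin(vg$h / vt[["range_m"]], 1)^3)
  expect_true(all(abs(vg$gamma - truth) / truth < 0.2))
})

test_that("independent seeds give distinct fields with consistent range", {
  fit_range <- function(seed) {
    f <- gen_ndvi_field(scene_config(seed = seed))
    vg <- fluxrep:::empirical_variogram_matrix(
      f$values, cell = f$cell, direction = "omni", max_lag = 500
    )
    fit_spherical(vg)$range_m
  }
  f1 <- gen_ndvi_field(scene_config(seed = 21))
  f2 <- gen_ndvi_field(scene_config(seed = 22))
  expect_false(identical(f1$values, f2$values))
  r1 <- fit_range(21)
  r2 <- fit_range(22)
  expect_lt(abs(r1 - r2) / r1, 0.2)
})

test_that("sigma_v training generator calibrates its attainable skill", {
  cfg <- scene_config(seed = 3)
  tr <- gen_sigma_v_training(cfg, n = 2000)
  expect_identical(tr, gen_sigma_v_training(cfg, n = 2000))
  expect_equal(attr(tr, "attainable_r2"), 0.78, tolerance = 1e-12)
  expect_true(attr(tr, "noise_sd") > 0)
  expect_named(tr, c("ustar", "ws", "sw_in", "pa", "z0", "zm", "hc",
                     "sigma_v"))

  tr0 <- gen_sigma_v_training(cfg, n = 2000, noise_sd = 0)
  expect_equal(attr(tr0, "attainable_r2"), 1)
  m0 <- fit_sigma_v(tr0, folds = 5, seed = 1)
  expect_gt(m0$cv_r2, 0.99)
})

test_that("rasters round-trip through the ASCII grid format", {
  cfg <- small_scene()
  lc <- gen_landcover_raster(cfg)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(lc, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, lc$values)
  expect_equal(back$cell, lc$cell)
  expect_equal(back$half_width, lc$half_width)
})

test_that("scene configuration round-trips through YAML", {
  cfg <- scene_config(seed = 13, n_halfhours = 200)
  path <- withr::local_tempfile(fileext = ".yml")
  write_scene_config(cfg, path)
  back <- read_scene_config(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$wind_rose, cfg$wind_rose)
  expect_equal(back$stability_mix, cfg$stability_mix)
  expect_equal(back$variogram_truth, cfg$variogram_truth)
  expect_identical(gen_met_series(back), gen_met_series(cfg))
})
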