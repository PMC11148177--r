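#' Synthetic scene configuration
#'
#' Bundles everything needed to generate a self-consistent synthetic study
#' site: a half-hourly micrometeorological regime, a patchy categorical
#' land-cover raster, an NDVI field with a prescribed spherical spatial
#' covariance, and training data for the lateral-wind-speed predictor. The
#' generators are pure functions of this configuration, so a seed fixes the
#' whole scene.
#'
#' @param seed integer seed driving every generator.
#' @param n_halfhours number of half-hourly records to generate.
#' @param wind_rose data frame with columns `bearing` (degrees, direction the
#'   wind comes from) and `prob` (mixture weights summing to 1). Directions
#'   are jittered around each mode with a wrapped-normal spread.
#' @param wind_rose_sd angular spread (degrees) around each rose mode.
#' @param stability_mix named fractions `c(unstable=, neutral=, stable=)`
#'   summing to 1.
#' @param half_width raster half-width in metres. The default 2100 m
#'   approximates a +-0.02 degree window and is exactly divisible by both
#'   cell sizes.
#' @param cell_landcover,cell_ndvi cell sides in metres (30 m categorical
#'   land cover, 10 m NDVI).
#' @param variogram_truth named vector `c(nugget=, sill=, range_m=)` of the
#'   NDVI field's spherical variogram.
#' @param ndvi_mean mean NDVI of the synthetic field.
#' @param landcover_patches list of patch specs painted in order. The first
#'   must be `list(class = <code>)` (the background fill); later entries are
#'   `list(class=, type="disc", x=, y=, r=)`,
#'   `list(class=, type="rect", xmin=, xmax=, ymin=, ymax=)` or
#'   `list(class=, type="halfplane", bearing=, offset=)` (keeps cells whose
#'   signed distance along `bearing` exceeds `offset`).
#' @param tower list with `zm` (measurement height, m), `hc` (canopy height,
#'   m) and `igbp` (site IGBP code) of the synthetic tower.
#' @param sigma_v_noise_sd measurement noise added to the lateral wind speed
#'   in the met series (m s^-1).
#' @param sigma_v_frac_present fraction of met records that carry a measured
#'   `sigma_v`; the rest are left missing for the predictor to fill.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(seed = 1L,
                         n_halfhours = 8000L,
                         wind_rose = data.frame(
                           bearing = c(225, 45),
                           prob = c(0.65, 0.35)
                         ),
                         wind_rose_sd = 25,
                         stability_mix = c(
                           unstable = 0.5, neutral = 0.2, stable = 0.3
                         ),
                         half_width = 2100,
                         cell_landcover = 30,
                         cell_ndvi = 10,
                         variogram_truth = c(
                           nugget = 2e-4, sill = 1e-3, range_m = 240
                         ),
                         ndvi_mean = 0.45,
                         landcover_patches = list(
                           list(class = 70),
                           list(class = 130, type = "disc",
                                x = 450, y = 450, r = 300),
                           list(class = 10, type = "rect",
                                xmin = -2100, xmax = 2100,
                                ymin = -2100, ymax = -1500)
                         ),
                         tower = list(zm = 40, hc = 18, igbp = 1L),
                         sigma_v_noise_sd = 0.03,
                         sigma_v_frac_present = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_halfhours = as.integer(n_halfhours),
    wind_rose = as_tibble(wind_rose), wind_rose_sd = wind_rose_sd,
    stability_mix = stability_mix, half_width = half_width,
    cell_landcover = cell_landcover, cell_ndvi = cell_ndvi,
    variogram_truth = variogram_truth, ndvi_mean = ndvi_mean,
    landcover_patches = landcover_patches, tower = tower,
    sigma_v_noise_sd = sigma_v_noise_sd,
    sigma_v_frac_present = sigma_v_frac_present
  )
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  if (abs(sum(cfg$wind_rose$prob) - 1) > 1e-9) {
    abort("wind_rose probabilities must sum to 1.")
  }
  sm <- cfg$stability_mix
  if (length(sm) != 3L || any(sm < 0) || abs(sum(sm) - 1) > 1e-9) {
    abort("stability_mix must be three non-negative fractions summing to 1.")
  }
  vt <- cfg$variogram_truth
  if (vt[["nugget"]] < 0 || vt[["sill"]] < vt[["nugget"]] ||
      vt[["range_m"]] <= 0) {
    abort("variogram_truth needs 0 <= nugget <= sill and range_m > 0.")
  }
  for (cell in c(cfg$cell_landcover, cfg$cell_ndvi)) {
    if (abs((2 * cfg$half_width / cell) %% 1) > 1e-9) {
      abort(sprintf("cell size %g m must divide the %g m extent.",
                    cell, 2 * cfg$half_width))
    }
  }
  known <- glc_igbp_map()$glc_code
  for (p in cfg$landcover_patches) {
    if (!p$class %in% known) {
      abort(sprintf("unknown land-cover class code %s.", p$class))
    }
  }
  if (cfg$n_halfhours < 1L) abort("n_halfhours must be >= 1.")
  structure(cfg, class = "scene_config")
}

# deterministic sub-seed per generator so generators are independent of the
# order in which they are called
scene_seed <- function(cfg, stage) {
  offsets <- c(met = 11L, landcover = 23L, ndvi = 37L, sigma_v = 53L)
  (cfg$seed * 101L + offsets[[stage]]) %% .Machine$integer.max
}

# Smooth generating function for the lateral wind speed standard deviation.
# Dominated by friction velocity with a mild wind-speed interaction; the
# remaining covariates contribute weak but non-zero signal so that a
# regression over all seven inputs is identifiable. Documented here because
# the analytically attainable R^2 of any predictor is computed from it.
sigma_v_signal <- function(ustar, ws, sw_in, pa, z0, zm, hc) {
  0.15 + 1.1 * ustar + 0.04 * ws + 0.10 * ustar * ws +
    8e-5 * sw_in + 0.004 * (pa - 95) + 0.05 * z0 / (1 + z0) +
    0.002 * (zm - hc)
}

#' Generate a half-hourly micrometeorological series
#'
#' Draws `n_halfhours` records with the joint structure the footprint model
#' expects: a mixed wind rose, a configurable stability mix (unstable records
#' get positive sensible heat flux and hence negative Obukhov length, stable
#' the reverse, neutral a near-zero flux and very long `L`), friction
#' velocity tied to wind speed, and a lateral wind speed generated from
#' the documented smooth function of the met drivers plus noise. A fraction
#' of `sigma_v` values is withheld (set `NA`) to emulate towers without
#' lateral-wind statistics.
#'
#' @param config a [scene_config()].
#' @return tibble with columns `timestamp, ws, wd, ustar, sigma_v, L, pblh,
#'   sw_in, pa, ta, h, regime`.
#' @export
gen_met_series <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$n_halfhours
  withr::with_seed(scene_seed(config, "met"), {
    regime <- sample(c("unstable", "neutral", "stable"), n, replace = TRUE,
                     prob = config$stability_mix)
    ws <- pmin(pmax(rlnorm(n, meanlog = 1.15, sdlog = 0.45), 0.3), 20)
    ustar <- pmin(pmax(0.08 * ws * (1 + 0.25 * rnorm(n)) + 0.05, 0.05), 1.5)
    mode <- sample.int(nrow(config$wind_rose), n, replace = TRUE,
                       prob = config$wind_rose$prob)
    wd <- (config$wind_rose$bearing[mode] +
             config$wind_rose_sd * rnorm(n)) %% 360
    sw_in <- c(
      unstable = NA, neutral = NA, stable = NA
    )
    sw_in <- dplyr::case_when(
      regime == "unstable" ~ runif(n, 200, 900),
      regime == "neutral" ~ runif(n, 50, 300),
      TRUE ~ runif(n, 0, 50)
    )
    ta <- rnorm(n, 12, 8)
    pa <- rnorm(n, 98, 1.5)
    h <- dplyr::case_when(
      regime == "unstable" ~ runif(n, 60, 350),
      regime == "neutral" ~ runif(n, -8, 8),
      TRUE ~ runif(n, -80, -10)
    )
    pblh <- dplyr::case_when(
      regime == "unstable" ~ runif(n, 800, 2200),
      regime == "neutral" ~ runif(n, 400, 1200),
      TRUE ~ runif(n, 150, 700)
    )
    tw <- config$tower
    z0 <- 0.1 * tw$hc
    sigma_v <- sigma_v_signal(ustar, ws, sw_in, pa, z0, tw$zm, tw$hc) +
      config$sigma_v_noise_sd * rnorm(n)
    sigma_v <- pmax(sigma_v, 0.02)
    sigma_v[runif(n) > config$sigma_v_frac_present] <- NA_real_
    tibble(
      timestamp = seq.POSIXt(
        as.POSIXct("2015-01-01 00:00:00", tz = "UTC"),
        by = "30 min", length.out = n
      ),
      ws = ws, wd = wd, ustar = ustar, sigma_v = sigma_v,
      L = obukhov_length(ustar, ta, pa, h),
      pblh = pblh, sw_in = sw_in, pa = pa, ta = ta, h = h,
      regime = regime
    )
  })
}

paint_patch <- function(mask_xy, patch) {
  x <- mask_xy$x
  y <- mask_xy$y
  type <- patch$type %||% "fill"
  switch(type,
    fill = x == x,
    disc = (x - patch$x)^2 + (y - patch$y)^2 <= patch$r^2,
    rect = x >= patch$xmin & x <= patch$xmax &
      y >= patch$ymin & y <= patch$ymax,
    halfplane = {
      b <- patch$bearing * pi / 180
      x * sin(b) + y * cos(b) >= patch$offset
    },
    abort(sprintf("unknown patch type '%s'.", type))
  )
}

#' Generate a categorical land-cover raster
#'
#' Paints the configured patches, in order, onto a 30 m grid of GLC-style
#' integer class codes. The first patch is the background fill. Geometry is
#' deterministic; the raster depends on the seed only through the config.
#'
#' @param config a [scene_config()].
#' @return a `flux_raster` of integer class codes (subclass
#'   `landcover_raster`).
#' @export
gen_landcover_raster <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- as.integer(2 * config$half_width / config$cell_landcover)
  vals <- matrix(NA_real_, n, n)
  r <- flux_raster(vals, config$cell_landcover, "landcover_raster")
  xy <- raster_xy(r)
  for (p in config$landcover_patches) {
    sel <- paint_patch(xy, p)
    r$values[sel] <- p$class
  }
  r
}

# Stationary Gaussian random field on an n x n torus via circulant embedding
# (FFT). Covariance follows the spherical model's structured part; wrap-around
# correlation is negligible while range << domain, and any small negative
# embedding eigenvalues are clamped to zero, so the covariance is matched
# approximately (tolerances asserted in tests).
simulate_grf_spherical <- function(n, cell, partial_sill, range_m) {
  if (partial_sill <= 0) {
    return(matrix(0, n, n))
  }
  idx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * cell
  dx <- matrix(idx, n, n)
  dy <- matrix(idx, n, n, byrow = TRUE)
  h <- sqrt(dx^2 + dy^2)
  u <- pmin(h / range_m, 1)
  cov <- partial_sill * (1 - 1.5 * u + 0.5 * u^3)
  lambda <- Re(stats::fft(cov))
  lambda[lambda < 0] <- 0
  z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  f <- stats::fft(sqrt(lambda) * z, inverse = TRUE)
  # the real and imaginary parts are two independent fields with the target
  # covariance; keep the real one (scaling: Cov(Re f) = sqrt(N)^2 * Gamma)
  Re(f) / n
}

#' Generate an NDVI field with prescribed spherical covariance
#'
#' Simulates a Gaussian random field whose semivariogram follows the
#' configured spherical model (structured part of variance `sill - nugget`,
#' range `range_m`) plus independent cell noise of variance `nugget`, adds
#' the configured mean, and clips to the NDVI domain `[-1, 1]`. With
#' `sill = 0` the field is constant at the mean.
#'
#' @param config a [scene_config()].
#' @return a `flux_raster` (subclass `ndvi_raster`) at the NDVI resolution.
#' @export
gen_ndvi_field <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  vt <- config$variogram_truth
  n <- as.integer(2 * config$half_width / config$cell_ndvi)
  withr::with_seed(scene_seed(config, "ndvi"), {
    field <- simulate_grf_spherical(
      n, config$cell_ndvi,
      partial_sill = vt[["sill"]] - vt[["nugget"]],
      range_m = vt[["range_m"]]
    )
    if (vt[["nugget"]] > 0) {
      field <- field + sqrt(vt[["nugget"]]) * matrix(rnorm(n * n), n, n)
    }
    vals <- pmin(pmax(config$ndvi_mean + field, -1), 1)
    flux_raster(vals, config$cell_ndvi, "ndvi_raster")
  })
}

#' Split an NDVI field into synthetic NIR and red bands
#'
#' Inverse of the normalized-difference formula at a fixed brightness
#' `b = nir + red`: `nir = b (1 + ndvi) / 2`, `red = b (1 - ndvi) / 2`.
#' Useful for exercising the band arithmetic on fields with known NDVI.
#'
#' @param ndvi a `flux_raster` of NDVI values.
#' @param brightness the band sum `nir + red`.
#' @return list with `flux_raster`s `nir` and `red`.
#' @export
ndvi_to_bands <- function(ndvi, brightness = 0.5) {
  nir <- ndvi
  red <- ndvi
  nir$values <- brightness * (1 + ndvi$values) / 2
  red$values <- brightness * (1 - ndvi$values) / 2
  list(nir = nir, red = red)
}

#' Generate training data for the lateral-wind-speed predictor
#'
#' Draws the seven covariates (friction velocity, wind speed, incoming
#' shortwave, pressure, roughness length, measurement height, canopy height)
#' over realistic ranges and computes `sigma_v` from the documented smooth
#' generating function plus Gaussian noise. With `noise_sd = NULL` the noise
#' is calibrated analytically so that the best attainable cross-validated
#' R^2 of any predictor equals `target_r2`:
#' `noise_sd = sd(signal) * sqrt((1 - target_r2) / target_r2)`.
#'
#' @param config a [scene_config()].
#' @param n number of training rows.
#' @param noise_sd noise standard deviation (m s^-1), or `NULL` to calibrate.
#' @param target_r2 attainable R^2 used when calibrating.
#' @return tibble with the 7 covariates and `sigma_v`; attributes
#'   `noise_sd` and `attainable_r2` record the generator's own ceiling.
#' @export
gen_sigma_v_training <- function(config, n = 6000L, noise_sd = NULL,
                                 target_r2 = 0.78) {
  stopifnot(inherits(config, "scene_config"), n >= 1000L)
  withr::with_seed(scene_seed(config, "sigma_v"), {
    ws <- pmin(pmax(rlnorm(n, 1.15, 0.5), 0.3), 22)
    ustar <- pmin(pmax(0.08 * ws * (1 + 0.3 * rnorm(n)) + 0.05, 0.05), 1.5)
    sw_in <- runif(n, 0, 950)
    pa <- rnorm(n, 97, 3)
    hc <- 10^runif(n, -1, 1.4)
    z0 <- 0.1 * hc
    zm <- hc + runif(n, 2, 30)
    signal <- sigma_v_signal(ustar, ws, sw_in, pa, z0, zm, hc)
    if (is.null(noise_sd)) {
      noise_sd <- sd(signal) * sqrt((1 - target_r2) / target_r2)
    }
    sigma_v <- pmax(signal + noise_sd * rnorm(n), 0.01)
    out <- tibble(
      ustar = ustar, ws = ws, sw_in = sw_in, pa = pa,
      z0 = z0, zm = zm, hc = hc, sigma_v = sigma_v
    )
    attr(out, "noise_sd") <- noise_sd
    attr(out, "attainable_r2") <-
      var(signal) / (var(signal) + noise_sd^2)
    out
  })
}

#' Circular mean of directions in degrees
#'
#' @param deg directions in degrees.
#' @return mean bearing in `[0, 360)`.
#' @export
circular_mean <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

#' Write a met series as a FLUXNET-style CSV
#'
#' Uses FULLSET-like column names (`TIMESTAMP_START`, `WS_F`, `WD`, `USTAR`,
#' `SW_IN_F`, `PA_F`, `TA_F`, `H_F`, plus `SIGMA_V`, `PBLH`); missing values
#' are written as -9999.
#'
#' @param records met tibble as from [gen_met_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fluxnet_csv <- function(records, path) {
  out <- tibble(
    TIMESTAMP_START = format(records$timestamp, "%Y%m%d%H%M"),
    WS_F = records$ws, WD = records$wd, USTAR = records$ustar,
    SIGMA_V = records$sigma_v, SW_IN_F = records$sw_in,
    PA_F = records$pa, TA_F = records$ta, H_F = records$h,
    PBLH = records$pblh
  )
  out <- mutate(out, across(where(is.numeric), ~ ifelse(is.na(.x), -9999, .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write / read a scene configuration as YAML
#'
#' Serializes everything needed to regenerate a scene (the wind rose and
#' patch list included) so a run can be reproduced from a flat text file.
#'
#' @param config a [scene_config()].
#' @param path YAML file path.
#' @return `path`, invisibly (writer); a `scene_config` (reader).
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  out <- unclass(config)
  out$wind_rose <- as.list(as.data.frame(config$wind_rose))
  out$stability_mix <- as.list(config$stability_mix)
  out$variogram_truth <- as.list(config$variogram_truth)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scene_config(
    seed = raw$seed, n_halfhours = raw$n_halfhours,
    wind_rose = as.data.frame(raw$wind_rose),
    wind_rose_sd = raw$wind_rose_sd,
    stability_mix = unlist(raw$stability_mix),
    half_width = raw$half_width,
    cell_landcover = raw$cell_landcover, cell_ndvi = raw$cell_ndvi,
    variogram_truth = unlist(raw$variogram_truth),
    ndvi_mean = raw$ndvi_mean,
    landcover_patches = raw$landcover_patches,
    tower = raw$tower,
    sigma_v_noise_sd = raw$sigma_v_noise_sd,
    sigma_v_frac_present = raw$sigma_v_frac_present
  )
}
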