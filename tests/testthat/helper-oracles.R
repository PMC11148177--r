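# Shared fixtures and independent oracles used across the suite.

# reference footprint drivers: moderately unstable, mid-height tower
ref_meta <- function() {
  site_meta("REF", igbp = 1L, lat = 56, lon = 10, zm = 20, hc = 1,
            z0 = 0.1, d = 0)
}

ref_record <- function(wd = 270, L = -100, ustar = 0.3, sigma_v = 0.4,
                       ws = 3, pblh = 1500) {
  tibble::tibble(ws = ws, wd = wd, ustar = ustar, sigma_v = sigma_v,
                 L = L, pblh = pblh)
}

# tower-centred isotropic Gaussian climatology
gaussian_acfc <- function(sigma, cell, half_width) {
  xs <- seq(-half_width + cell / 2, half_width - cell / 2, by = cell)
  g <- outer(rev(xs), xs, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  flux_raster(g / sum(g), cell, "acfc")
}

# closed-form peak distance and r-fetch of the crosswind-integrated
# parameterized curve F* = a (X*-d)^b exp(-c/(X*-d)): its cumulative is an
# upper incomplete gamma function of c/(X*-d) with shape -b-1, normalized
# over the conventional evaluation span X* <= 30. Independent of the
# package's numeric grid/trapezoid route.
ffp_closed_form <- function(zm, z0, d, L, pblh, r = 0.8, xstar_max = 30) {
  a <- 1.4524
  b <- -1.9914
  cc <- 1.4622
  dd <- 0.1359
  shape <- -b - 1
  zmd <- zm - d
  psi <- if (L > 0) {
    -5.3 * zmd / L
  } else {
    x <- (1 - 19 * zmd / L)^0.25
    log((1 + x^2) / 2) + 2 * log((1 + x) / 2) - 2 * atan(x) + pi / 2
  }
  scale <- zmd * (log(zmd / z0) - psi) / (1 - zmd / pblh)
  q_end <- pgamma(cc / (xstar_max - dd), shape, lower.tail = FALSE)
  s_r <- qgamma(r * q_end, shape, lower.tail = FALSE)
  list(
    peak_m = (dd - cc / b) * scale,
    fetch_m = (dd + cc / s_r) * scale
  )
}

# brute-force all-pairs semivariogram over a matrix field (the Eq.-style
# estimator written as an explicit double loop over cells)
naive_variogram <- function(values, mask = NULL, weights = NULL, cell = 1,
                            direction = "omni", max_lag = NULL,
                            weighted = FALSE, angle_tol = 22.5) {
  centers <- c("NS" = 0, "NE-SW" = 45, "EW" = 90, "NW-SE" = 135)
  if (is.null(mask)) mask <- !is.na(values)
  idx <- which(mask & !is.na(values), arr.ind = TRUE)
  if (is.null(max_lag)) {
    dr <- diff(range(idx[, 1])) + 1
    dc <- diff(range(idx[, 2])) + 1
    max_lag <- cell * sqrt(dr^2 + dc^2) / 2
  }
  kmax <- floor(max_lag / cell)
  ssum <- numeric(kmax)
  wsum <- numeric(kmax)
  npair <- numeric(kmax)
  for (p in seq_len(nrow(idx) - 1)) {
    for (q in (p + 1):nrow(idx)) {
      di <- idx[q, 1] - idx[p, 1]
      dj <- idx[q, 2] - idx[p, 2]
      dist <- sqrt(di^2 + dj^2)
      bin <- round(dist)
      if (bin < 1 || bin > kmax) next
      if (direction != "omni") {
        ang <- (atan2(dj, -di) * 180 / pi) %% 180
        dv <- abs(ang - centers[[direction]])
        dv <- min(dv, 180 - dv)
        if (dv >= angle_tol) next
      }
      d2 <- (values[idx[p, 1], idx[p, 2]] - values[idx[q, 1], idx[q, 2]])^2
      if (weighted) {
        w <- weights[idx[p, 1], idx[p, 2]] * weights[idx[q, 1], idx[q, 2]]
        ssum[bin] <- ssum[bin] + w * d2
        wsum[bin] <- wsum[bin] + w
      } else {
        ssum[bin] <- ssum[bin] + d2
      }
      npair[bin] <- npair[bin] + 1
    }
  }
  has <- npair > 0
  gamma <- if (weighted) ssum / (2 * wsum) else ssum / (2 * npair)
  tibble::tibble(h = (seq_len(kmax) * cell)[has], gamma = gamma[has],
                 n_pairs = npair[has])
}

# small scene configuration for fast pipeline tests
small_scene <- function(seed = 5, n_halfhours = 120L, ...) {
  scene_config(seed = seed, n_halfhours = n_halfhours, cell_ndvi = 20,
               ...)
}
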