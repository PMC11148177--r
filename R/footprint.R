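# Published fitted constants of the two-dimensional flux footprint
# parameterization: crosswind-integrated curve F*(X*) = a (X*-d)^b
# exp(-c / (X*-d)) and scaled crosswind spread
# sigma_y*(X*) = ac sqrt(bc X*^2 / (1 + cc X*)). Taken verbatim from the
# parameterization's source publication, not re-fitted.
.ffp <- list(
  a = 1.4524, b = -1.9914, c = 1.4622, d = 0.1359,
  ac = 2.17, bc = 1.66, cc = 20,
  xstar_max = 30
)

#' Footprint grid specification
#'
#' @param cell cell side in metres (default 10 m, matching the NDVI export
#'   resolution).
#' @param half_width grid half-width in metres.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(cell = 10, half_width = 2000) {
  stopifnot(cell > 0, half_width > cell)
  structure(list(cell = cell, half_width = half_width), class = "grid_spec")
}

# stability correction for the log wind profile (integral form),
# evaluated at zmd = zm - d
ffp_psi <- function(zmd, L) {
  if (!is.finite(L) || L > 0) {
    if (!is.finite(L)) return(0)
    -5.3 * zmd / L
  } else {
    x <- (1 - 19 * zmd / L)^0.25
    log((1 + x^2) / 2) + 2 * log((1 + x) / 2) - 2 * atan(x) + pi / 2
  }
}

# scaling factors shared by the profile and the 2-D field
ffp_scaling <- function(zm, z0, d, L, pblh) {
  zmd <- zm - d
  if (zmd <= 0) abort("zm must exceed the displacement height d.")
  if (zmd >= pblh) abort("zm must lie below the boundary-layer height.")
  psi <- ffp_psi(zmd, L)
  denom <- log(zmd / z0) - psi
  if (!is.finite(denom) || denom <= 0) {
    abort("log(zm/z0) - psi must be positive; record outside the parameterization's validity range.")
  }
  list(zmd = zmd, denom = denom, bl = 1 - zmd / pblh)
}

# crosswind-integrated footprint density (m^-1) at upwind distances x
ffp_fci <- function(x, sc) {
  xstar <- x * sc$bl / (sc$zmd * sc$denom)
  f <- numeric(length(x))
  ok <- is.finite(xstar) & xstar > .ffp$d
  t <- xstar[ok] - .ffp$d
  fstar <- .ffp$a * t^.ffp$b * exp(-.ffp$c / t)
  f[ok] <- fstar * sc$bl / (sc$zmd * sc$denom)
  f
}

# crosswind plume standard deviation (m) at upwind distances x
ffp_sigy <- function(x, sc, sigma_v, ustar, L) {
  xstar <- x * sc$bl / (sc$zmd * sc$denom)
  xstar[xstar < 0] <- 0
  sigystar <- .ffp$ac * sqrt(.ffp$bc * xstar^2 / (1 + .ffp$cc * xstar))
  ps <- 1e-5 * abs(sc$zmd / L)^(-1) + if (is.finite(L) && L > 0) 0.55 else 0.8
  ps <- min(ps, 1)
  sigystar / ps * sc$zmd * sigma_v / ustar
}

check_record_valid <- function(record, meta) {
  if (is.na(record$sigma_v)) abort("record has no sigma_v; predict it first.")
  if (record$L < 0 && meta$zm / record$L < -15.5) {
    abort("record violates the stability bound zm/L >= -15.5.")
  }
  if (20 * meta$z0 >= meta$zm) {
    abort("record violates the lower height bound 20*z0 < zm.")
  }
  if (meta$zm >= 0.8 * record$pblh) {
    abort("record violates the upper height bound zm < 0.8*pblh.")
  }
  invisible(TRUE)
}

#' Half-hourly two-dimensional flux footprint
#'
#' Evaluates the parameterized footprint on a tower-centred metric grid:
#' the crosswind-integrated density follows the published power-law times
#' exponential curve in scaled upwind distance, the crosswind distribution
#' is Gaussian with a parameterized spread growing with distance, and the
#' streamwise axis is rotated so the source area lies toward the bearing the
#' wind comes from (`wd`). Weights are densities per square metre; their sum
#' times the cell area approaches 1 as the domain grows.
#'
#' @param record one-row met tibble (or list) with `ws`, `wd`, `ustar`,
#'   `sigma_v`, `L`, `pblh`. The record must satisfy the validity bounds
#'   enforced by [qc_filter()]; violations raise an error naming the rule.
#' @param meta a [site_meta()] row.
#' @param grid a [grid_spec()].
#' @return a `flux_raster` of subclass `footprint_grid`, with the driving
#'   variables stored in the `"meta"` attribute.
#' @export
halfhour_footprint <- function(record, meta, grid = grid_spec()) {
  check_record_valid(record, meta)
  sc <- ffp_scaling(meta$zm, meta$z0, meta$d, record$L, record$pblh)
  n <- as.integer(round(2 * grid$half_width / grid$cell))
  r <- flux_raster(matrix(0, n, n), grid$cell, "footprint_grid")
  xy <- raster_xy(r)
  b <- record$wd * pi / 180
  xr <- xy$x * sin(b) + xy$y * cos(b)   # along-wind (towards the source)
  yr <- xy$x * cos(b) - xy$y * sin(b)   # crosswind
  fci <- ffp_fci(as.vector(xr), sc)
  sigy <- ffp_sigy(as.vector(xr), sc, record$sigma_v, record$ustar, record$L)
  w <- numeric(length(fci))
  ok <- fci > 0 & sigy > 0
  w[ok] <- fci[ok] * dnorm(as.vector(yr)[ok], 0, sigy[ok])
  r$values <- matrix(w, n, n)
  attr(r, "meta") <- list(
    zm = meta$zm, z0 = meta$z0, d = meta$d, ws = record$ws, wd = record$wd,
    ustar = record$ustar, sigma_v = record$sigma_v, L = record$L,
    pblh = record$pblh
  )
  r
}

#' Crosswind-integrated footprint profile
#'
#' The one-dimensional footprint density along the upwind distance axis,
#' exposed separately from the 2-D grid for testing and for fetch
#' diagnostics.
#'
#' @inheritParams halfhour_footprint
#' @param x upwind distances in metres (>= 0).
#' @return tibble with columns `x` and `f` (density per metre).
#' @export
crosswind_integrated_profile <- function(record, meta, x) {
  check_record_valid(record, meta)
  sc <- ffp_scaling(meta$zm, meta$z0, meta$d, record$L, record$pblh)
  tibble(x = x, f = ffp_fci(x, sc))
}

#' Peak distance and source-area fetch of a single footprint
#'
#' Computes, by trapezoid integration of the crosswind-integrated profile,
#' the distance of maximum contribution and the upwind distance enclosing a
#' fraction `r` of the footprint. Following the reference convention for
#' this parameterization, the profile is evaluated out to the scaled
#' distance `X* = 30` and the cumulative integral is normalized over that
#' span (the curve's power-law tail makes an unbounded normalization
#' unusable on any finite domain).
#'
#' @inheritParams halfhour_footprint
#' @param r enclosed fraction (default 0.8).
#' @param dx integration step in metres.
#' @return tibble with `peak_m` and `fetch_m`.
#' @export
footprint_extent <- function(record, meta, r = 0.8, dx = 1) {
  check_record_valid(record, meta)
  sc <- ffp_scaling(meta$zm, meta$z0, meta$d, record$L, record$pblh)
  x_end <- .ffp$xstar_max * sc$zmd * sc$denom / sc$bl
  x <- seq(0, x_end, by = dx)
  f <- ffp_fci(x, sc)
  cum <- cumsum((head(f, -1) + tail(f, -1)) / 2 * diff(x))
  cum <- cum / cum[length(cum)]
  tibble(
    peak_m = x[which.max(f)],
    fetch_m = x[min(which(cum >= r)) + 1L]
  )
}
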