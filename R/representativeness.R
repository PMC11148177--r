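#' Footprint-weighted mean NDVI
#'
#' Weighted sum of the NDVI pixels inside the chosen contour with the
#' footprint weights renormalized to 1 over that mask.
#'
#' @param ndvi an NDVI `flux_raster`.
#' @param acfc the footprint climatology.
#' @param contours the matching [extract_contours()] result.
#' @param level contour level (default 80).
#' @return scalar footprint-weighted NDVI.
#' @export
footprint_weighted_ndvi <- function(ndvi, acfc, contours, level = 80) {
  mask <- contours$masks[[as.character(level)]]
  if (is.null(mask) || !any(mask)) abort("empty contour mask.")
  xy <- raster_xy(acfc)
  w <- acfc$values[mask]
  v <- raster_sample(ndvi, xy$x[mask], xy$y[mask])
  ok <- !is.na(v)
  if (!any(ok)) abort("no NDVI values under the contour mask.")
  sum(w[ok] * v[ok]) / sum(w[ok])
}

#' Unweighted mean NDVI of the contour target area
#'
#' @inheritParams footprint_weighted_ndvi
#' @return scalar mean NDVI over the pixels inside the contour.
#' @export
target_mean_ndvi <- function(ndvi, contours, level = 80) {
  mask <- contours$masks[[as.character(level)]]
  if (is.null(mask) || !any(mask)) abort("empty contour mask.")
  n <- nrow(mask)
  cell <- contours$cell
  xs <- seq(-n / 2 * cell + cell / 2, n / 2 * cell - cell / 2, by = cell)
  ys <- rev(xs)
  idx <- which(mask, arr.ind = TRUE)
  v <- raster_sample(ndvi, xs[idx[, 2]], ys[idx[, 1]])
  mean(v, na.rm = TRUE)
}

#' Sensor location bias
#'
#' Relative difference between the footprint-weighted NDVI and the target
#' area's mean NDVI: `SLB = (NDVI_fp - NDVI_target) / NDVI_target`. The
#' ratio is undefined for a zero target mean, which is flagged with a
#' warning and returned as `NA`.
#'
#' @param ndvi_fp footprint-weighted NDVI.
#' @param ndvi_target target-area mean NDVI.
#' @return one-row tibble: `ndvi_fp`, `ndvi_target`, `slb`, `abs_slb`.
#' @export
sensor_location_bias <- function(ndvi_fp, ndvi_target) {
  if (ndvi_target == 0) {
    warn("ndvi_target is zero: SLB undefined.")
    slb <- NA_real_
  } else {
    slb <- (ndvi_fp - ndvi_target) / ndvi_target
  }
  tibble(
    ndvi_fp = ndvi_fp, ndvi_target = ndvi_target,
    slb = slb, abs_slb = abs(slb)
  )
}

#' Sensor location bias across square windows
#'
#' Target areas are tower-centred squares of side `l_i = 30 (2 i - 1)`
#' metres, `i = 1..n_windows` (30 m to 2970 m at the default 50 windows).
#' The target mean is the unweighted mean NDVI of cells whose centres fall
#' inside the square (cell-centre membership); the bias of the
#' footprint-weighted NDVI is computed against each window per the SLB
#' definition. Windows extending beyond the raster are truncated with a
#' warning.
#'
#' @param ndvi an NDVI `flux_raster`.
#' @param ndvi_fp footprint-weighted NDVI (e.g. from
#'   [footprint_weighted_ndvi()]).
#' @param n_windows number of windows.
#' @return a `window_profile` tibble: `i`, `side_m`, `target_mean`, `slb`,
#'   `abs_slb`.
#' @export
window_profile <- function(ndvi, ndvi_fp, n_windows = 50L) {
  i <- seq_len(n_windows)
  side <- 30 * (2 * i - 1)
  if (max(side) / 2 > ndvi$half_width) {
    warn("largest windows extend beyond the raster and are truncated.")
  }
  xy <- raster_xy(ndvi)
  target <- map_dbl(side, function(l) {
    sel <- abs(xy$x) <= l / 2 & abs(xy$y) <= l / 2
    mean(ndvi$values[sel], na.rm = TRUE)
  })
  out <- tibble(
    i = i, side_m = side, target_mean = target,
    slb = (ndvi_fp - target) / target
  ) |>
    mutate(abs_slb = abs(.data$slb))
  class(out) <- c("window_profile", class(out))
  out
}

level_band <- function(x, lo, hi, low_is_good) {
  # closed middle band: boundary values are Medium
  band <- ifelse(x < lo, 1L, ifelse(x > hi, 3L, 2L))
  if (low_is_good) band else 4L - band
}

#' Three-indicator representativeness classification
#'
#' Each indicator is banded into levels 1 (High), 2 (Medium), 3 (Low):
#' dominant-cover percentage (<50 Low, 50-80 Medium, >80 High),
#' omnidirectional nugget-to-sill ratio in percent (<25 High, 25-75 Medium,
#' >75 Low), and absolute sensor location bias (<0.05 High, 0.05-0.1
#' Medium, >0.1 Low). Band boundaries belong to the middle band.
#'
#' @param dominant_pct footprint-weighted percentage of the dominant cover
#'   type (0-100).
#' @param nugget_sill_ratio_pct omnidirectional nugget/sill ratio (0-100).
#' @param abs_slb absolute sensor location bias.
#' @return tibble with integer columns `rp`, `rs`, `rb` (vectorized).
#' @export
classify_site <- function(dominant_pct, nugget_sill_ratio_pct, abs_slb) {
  if (any(!is.finite(dominant_pct)) || any(!is.finite(nugget_sill_ratio_pct)) ||
      any(!is.finite(abs_slb))) {
    abort("classification inputs must be finite.")
  }
  if (any(nugget_sill_ratio_pct < 0 | nugget_sill_ratio_pct > 100)) {
    abort("nugget_sill_ratio_pct must lie in [0, 100].")
  }
  tibble(
    rp = level_band(dominant_pct, 50, 80, low_is_good = FALSE),
    rs = level_band(nugget_sill_ratio_pct, 25, 75, low_is_good = TRUE),
    rb = level_band(abs_slb, 0.05, 0.1, low_is_good = TRUE)
  )
}
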