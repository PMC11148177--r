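#' NDVI from red and near-infrared bands
#'
#' Cellwise normalized difference `(nir - red) / (nir + red)`; cells where
#' the band sum is zero are masked (`NA`).
#'
#' @param nir,red co-registered `flux_raster` bands.
#' @return a `flux_raster` of subclass `ndvi_raster`.
#' @export
compute_ndvi <- function(nir, red) {
  if (!identical(dim(nir$values), dim(red$values)) ||
      nir$cell != red$cell) {
    abort("nir and red bands must be co-registered.")
  }
  s <- nir$values + red$values
  v <- (nir$values - red$values) / s
  v[s == 0] <- NA_real_
  out <- nir
  out$values <- v
  class(out) <- c("ndvi_raster", "flux_raster")
  out
}

#' Annual composite of NDVI scenes
#'
#' Drops scenes with 5% cloud cover or more (strictly-less-than filter) and
#' averages the remainder cellwise over non-masked values.
#'
#' @param scenes list of co-registered NDVI `flux_raster`s.
#' @param cloud_pct scene-level cloud percentages, same length as `scenes`.
#' @return a composite `flux_raster`.
#' @export
annual_composite <- function(scenes, cloud_pct) {
  stopifnot(length(scenes) == length(cloud_pct))
  keep <- cloud_pct < 5
  if (!any(keep)) abort("all scenes dropped by the cloud filter.")
  scenes <- scenes[keep]
  vals <- map(scenes, "values")
  num <- reduce(map(vals, ~ ifelse(is.na(.x), 0, .x)), `+`)
  cnt <- reduce(map(vals, ~ !is.na(.x) * 1), `+`)
  out <- scenes[[1]]
  out$values <- ifelse(cnt > 0, num / cnt, NA_real_)
  out
}

variogram_directions <- c("EW" = 90, "NE-SW" = 45, "NS" = 0, "NW-SE" = 135)

# Empirical semivariogram of a matrix field. Pairs are enumerated as lag
# offsets between grid cells; each offset is handled by one vectorized
# shift of the overlapping sub-matrices, so all pairs are covered exactly
# (a brute-force all-pairs oracle check lives in the tests). Lag bins are
# one cell wide, centred on integer multiples of the cell size.
empirical_variogram_matrix <- function(values, mask = NULL, weights = NULL,
                                       cell = 1, direction = "omni",
                                       max_lag = NULL, weighted = FALSE,
                                       angle_tol = 22.5) {
  n_r <- nrow(values)
  n_c <- ncol(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & !is.na(values)
  if (sum(mask) < 2) abort("need at least 2 unmasked cells.")
  if (weighted && is.null(weights)) {
    abort("weighted mode needs a weight matrix.")
  }
  if (is.null(max_lag)) {
    idx <- which(mask, arr.ind = TRUE)
    dr <- diff(range(idx[, 1])) + 1L
    dc <- diff(range(idx[, 2])) + 1L
    max_lag <- cell * sqrt(dr^2 + dc^2) / 2
  }
  kmax <- floor(max_lag / cell)
  if (kmax < 1) abort("max_lag below one cell; no pairs to evaluate.")
  if (direction != "omni" && !direction %in% names(variogram_directions)) {
    abort("direction must be one of EW, NE-SW, NS, NW-SE, omni.")
  }
  nbin <- kmax
  ssum <- numeric(nbin)
  wsum <- numeric(nbin)
  npair <- numeric(nbin)
  for (di in -kmax:kmax) {
    for (dj in 0:kmax) {
      if (dj == 0 && di <= 0) next   # one of each unordered offset pair
      dist <- sqrt(di^2 + dj^2)
      bin <- round(dist)
      if (bin < 1 || bin > nbin || dist * cell > max_lag + cell / 2) next
      if (direction != "omni") {
        # separation vector in metric axes: east = dj, north = -di
        ang <- (atan2(dj, -di) * 180 / pi) %% 180
        ctr <- variogram_directions[[direction]]
        diff_ang <- abs(ang - ctr)
        diff_ang <- min(diff_ang, 180 - diff_ang)
        if (diff_ang >= angle_tol) next
      }
      r1 <- max(1L, 1L - di):min(n_r, n_r - di)
      c1 <- max(1L, 1L - dj):min(n_c, n_c - dj)
      r2 <- r1 + di
      c2 <- c1 + dj
      ok <- mask[r1, c1, drop = FALSE] & mask[r2, c2, drop = FALSE]
      if (!any(ok)) next
      d2 <- (values[r1, c1, drop = FALSE] - values[r2, c2, drop = FALSE])^2
      if (weighted) {
        w <- weights[r1, c1, drop = FALSE] * weights[r2, c2, drop = FALSE]
        ssum[bin] <- ssum[bin] + sum((w * d2)[ok])
        wsum[bin] <- wsum[bin] + sum(w[ok])
      } else {
        ssum[bin] <- ssum[bin] + sum(d2[ok])
      }
      npair[bin] <- npair[bin] + sum(ok)
    }
  }
  has <- npair > 0
  if (!any(has)) abort("no pairs found at any lag.")
  gamma <- if (weighted) {
    ifelse(wsum > 0, ssum / (2 * wsum), NA_real_)
  } else {
    ifelse(npair > 0, ssum / (2 * npair), NA_real_)
  }
  tibble(
    direction = direction,
    h = (seq_len(nbin) * cell)[has],
    gamma = gamma[has],
    n_pairs = npair[has],
    sum_w = if (weighted) wsum[has] else npair[has]
  )
}

#' Directional semivariogram of NDVI inside a footprint contour
#'
#' Estimates the experimental semivariogram of the NDVI field restricted to
#' the chosen climatology contour. In the default weighted mode each pair
#' contributes with the product of the footprint weights at its two pixels,
#' normalized per lag; in unweighted mode (`weighted = FALSE`) the estimator
#' is exactly the half mean squared difference over the pairs. Pairs are
#' assigned to one of four 45-degree sectors (East-West, Northeast-Southwest,
#' North-South, Northwest-Southeast, angular tolerance +-22.5 degrees so the
#' sectors tile the plane) or to the omnidirectional estimate. Lag bins are
#' one NDVI cell; the default maximum lag is half the diagonal of the mask's
#' bounding box.
#'
#' @param ndvi an NDVI `flux_raster`.
#' @param acfc the footprint climatology (same tower frame).
#' @param contours the matching [extract_contours()] result.
#' @param direction one of `"EW"`, `"NE-SW"`, `"NS"`, `"NW-SE"`, `"omni"`.
#' @param level contour level restricting the pixels.
#' @param weighted use footprint pair weights (default) or plain averaging.
#' @param max_lag maximum lag in metres.
#' @return a `variogram_estimate` tibble: `direction`, `h`, `gamma`,
#'   `n_pairs`, `sum_w`.
#' @export
directional_semivariogram <- function(ndvi, acfc, contours,
                                      direction = "EW", level = 80,
                                      weighted = TRUE, max_lag = NULL) {
  mask80 <- contours$masks[[as.character(level)]]
  if (is.null(mask80)) abort(sprintf("no %s%% contour in `contours`.", level))
  xy <- raster_xy(ndvi)
  inmask <- raster_sample(
    flux_raster(mask80 * 1, contours$cell), xy$x, xy$y
  )
  mask <- matrix(!is.na(inmask) & inmask > 0, nrow(ndvi$values))
  w <- raster_sample(acfc, xy$x, xy$y)
  w[is.na(w)] <- 0
  wm <- matrix(w, nrow(ndvi$values))
  out <- empirical_variogram_matrix(
    ndvi$values, mask = mask, weights = wm, cell = ndvi$cell,
    direction = direction, max_lag = max_lag, weighted = weighted
  )
  class(out) <- c("variogram_estimate", class(out))
  out
}

#' Average directional semivariograms to an omnidirectional estimate
#'
#' Per-lag arithmetic mean of the four directional estimates; pair counts
#' are summed. Lags present in only some directions are dropped so the
#' average is always over four values.
#'
#' @param vgms list of four `variogram_estimate`s on a common lag grid.
#' @return a `variogram_estimate` with `direction = "omni"`.
#' @export
omnidirectional_semivariogram <- function(vgms) {
  stopifnot(length(vgms) >= 2)
  common <- reduce(map(vgms, "h"), intersect)
  if (!length(common)) abort("no common lags across directions.")
  out <- purrr::list_rbind(map(vgms, ~ filter(.x, .data$h %in% common))) |>
    group_by(.data$h) |>
    summarise(
      gamma = mean(.data$gamma),
      n_pairs = sum(.data$n_pairs),
      sum_w = sum(.data$sum_w),
      .groups = "drop"
    ) |>
    mutate(direction = "omni", .before = 1)
  class(out) <- c("variogram_estimate", class(out))
  out
}

spherical_curve <- function(h, nugget, sill, range_m) {
  u <- pmin(h / range_m, 1)
  nugget + (sill - nugget) * (1.5 * u - 0.5 * u^3)
}

#' Fit a spherical model to an empirical semivariogram
#'
#' Weighted least squares (effective pair weights -- the pair counts for an
#' unweighted estimator) of
#' `gamma(h) = nugget + (sill - nugget) * (1.5 h/a - 0.5 (h/a)^3)` for
#' `h < a` and `sill` beyond, under the constraints
#' `0 <= nugget <= sill`, `a > 0`. Initial values: nugget from the first
#' lag, sill from the mean of the last third of lags, range from the first
#' lag reaching 95% of that sill. The fitted range is capped at 1.5 times
#' the maximum lag (beyond the observed window it is not identifiable). A
#' flat empirical variogram collapses to `nugget = sill` with the range at
#' its lower bound and is flagged.
#'
#' @param vgm a `variogram_estimate` with at least 4 lags.
#' @return a `spherical_fit`: `nugget`, `sill`, `range_m`,
#'   `nugget_sill_ratio` (percent), `converged`, `sse`, plus the data.
#' @export
fit_spherical <- function(vgm) {
  vgm <- filter(vgm, is.finite(.data$gamma))
  if (nrow(vgm) < 4) abort("need at least 4 lags to fit.")
  h <- vgm$h
  g <- vgm$gamma
  # least-squares weights: effective pair weights, which reduce to the pair
  # counts N(h) for the unweighted estimator; for footprint-weighted
  # variograms this keeps poorly-supported long lags from dominating
  w <- vgm$sum_w / sum(vgm$sum_w)
  sill0 <- mean(g[h >= stats::quantile(h, 2 / 3)])
  nug0 <- max(min(g[1], sill0), 0)
  range0 <- h[which(g >= 0.95 * sill0)[1]]
  if (is.na(range0)) range0 <- max(h) / 2
  gscale <- max(sill0, max(g), 1e-12)
  obj <- function(p) {
    nug <- p[1] * gscale
    psill <- p[2] * gscale
    a <- p[3] * max(h)
    sum(w * (spherical_curve(h, nug, nug + psill, a) - g)^2) / gscale^2
  }
  p0 <- c(nug0 / gscale, max(sill0 - nug0, 1e-6) / gscale,
          max(range0 / max(h), 0.05))
  # the range is not identifiable beyond the observed lag window; cap it
  # at 1.5x the maximum lag rather than letting the sill extrapolate freely
  lower <- c(0, 0, 1e-3)
  upper <- c(Inf, Inf, 1.5)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  fit <- optim(
    p0, function(p) obj(clamp(p)), method = "L-BFGS-B",
    lower = lower, upper = upper,
    control = list(maxit = 1000, factr = 1e4)
  )
  # code 52 (failed line search) occurs on objectives flat in the range
  # parameter; the derivative-free polish below resolves those
  if (!fit$convergence %in% c(0L, 52L)) {
    abort(sprintf("spherical fit did not converge (optim code %d: %s).",
                  fit$convergence, fit$message %||% ""))
  }
  # derivative-free polish (box enforced by clamping) for tight recovery
  polish <- optim(
    fit$par, function(p) obj(clamp(p)), method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-15)
  )
  par <- clamp(if (polish$value <= fit$value) polish$par else fit$par)
  fit$value <- min(polish$value, fit$value)
  nugget <- par[1] * gscale
  sill <- nugget + par[2] * gscale
  range_m <- par[3] * max(h)
  degenerate <- sill <= 0 || (sill - nugget) <= 1e-3 * sill ||
    par[3] <= 1e-3 + 1e-9
  if (degenerate) {
    # no resolvable spatial structure: collapse to the pure-nugget model
    nugget <- sill <- sum(w * g) / sum(w)
    range_m <- h[1]
    warn("flat or degenerate variogram: pure nugget, range at its lower bound.")
  }
  structure(
    list(
      nugget = nugget, sill = sill, range_m = range_m,
      nugget_sill_ratio = if (sill > 0) 100 * nugget / sill else 100,
      converged = fit$convergence == 0, degenerate = degenerate,
      sse = fit$value, data = vgm
    ),
    class = "spherical_fit"
  )
}

#' @export
print.spherical_fit <- function(x, ...) {
  cat(sprintf(
    "<spherical_fit> nugget %.3g, sill %.3g, range %.1f m (nugget/sill %.1f%%)\n",
    x$nugget, x$sill, x$range_m, x$nugget_sill_ratio
  ))
  invisible(x)
}

#' @rdname fit_spherical
#' @param x a `spherical_fit`.
#' @param ... unused.
#' @export
tidy.spherical_fit <- function(x, ...) {
  tibble(
    term = c("nugget", "sill", "range_m"),
    estimate = c(x$nugget, x$sill, x$range_m)
  )
}

#' @rdname fit_spherical
#' @export
glance.spherical_fit <- function(x, ...) {
  tibble(
    nugget = x$nugget, sill = x$sill, range_m = x$range_m,
    nugget_sill_ratio = x$nugget_sill_ratio,
    sse = x$sse, converged = x$converged, n_lags = nrow(x$data)
  )
}

#' @rdname fit_sigma_v
#' @param x a `sigma_v_model`.
#' @param ... unused.
#' @export
tidy.sigma_v_model <- function(x, ...) {
  imp <- x$model$variable.importance
  tibble(term = names(imp), importance = unname(imp)) |>
    arrange(desc(.data$importance))
}

#' @rdname fit_sigma_v
#' @export
glance.sigma_v_model <- function(x, ...) {
  tibble(
    cv_r2 = x$cv_r2, cv_mae = x$cv_mae, cv_folds = x$cv_folds,
    num_trees = x$model$num.trees, n = x$n
  )
}
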