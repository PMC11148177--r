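#' Plot a footprint climatology with its percentile contours
#'
#' @param object an `acfc` raster.
#' @param contours optional [extract_contours()] result to overlay.
#' @param trans transformation for the fill scale.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.acfc <- function(object, contours = NULL, trans = "sqrt", ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_raster(aes(fill = .data$value)) +
    scale_fill_viridis_c(trans = trans, name = "weight") +
    coord_equal() +
    labs(x = "east (m)", y = "north (m)") +
    theme_minimal()
  if (!is.null(contours)) {
    p <- p + geom_path(
      data = contours$boundaries,
      aes(group = interaction(.data$level, .data$piece),
          colour = factor(.data$level)),
      linewidth = 0.4
    ) +
      scale_colour_brewer(palette = "OrRd", name = "contour %")
  }
  p
}

#' Plot an empirical semivariogram, optionally with a spherical fit
#'
#' @param object a `variogram_estimate`.
#' @param fit optional [fit_spherical()] result drawn as a curve.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.variogram_estimate <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$h, y = .data$gamma)) +
    geom_point(aes(size = .data$n_pairs), alpha = 0.7) +
    scale_size_area(name = "pairs", max_size = 3) +
    labs(x = "lag h (m)", y = expression(hat(gamma)(h)),
         title = unique(object$direction)) +
    theme_minimal()
  if (!is.null(fit)) {
    hh <- seq(0, max(object$h), length.out = 200)
    p <- p + geom_line(
      data = tibble(h = hh,
                    gamma = spherical_curve(hh, fit$nugget, fit$sill,
                                            fit$range_m)),
      colour = "firebrick"
    )
  }
  p
}

#' Plot the window-size sensor-location-bias profile
#'
#' Window-mean NDVI and |SLB| against window side length.
#'
#' @param object a [window_profile()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.window_profile <- function(object, ...) {
  long <- object |>
    select("side_m", "target_mean", "abs_slb") |>
    pivot_longer(-"side_m", names_to = "metric")
  ggplot(long, aes(x = .data$side_m, y = .data$value)) +
    geom_point() +
    geom_line(alpha = 0.5) +
    facet_wrap(~metric, scales = "free_y", ncol = 1,
               labeller = labeller(metric = c(
                 target_mean = "window-mean NDVI",
                 abs_slb = "|SLB| vs footprint-weighted NDVI"
               ))) +
    labs(x = "window side (m)", y = NULL) +
    theme_minimal()
}
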