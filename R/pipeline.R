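#' Run the full representativeness pipeline on a synthetic scene
#'
#' Executes every stage end to end: scene generation (met series, land
#' cover, NDVI), Obukhov-length and boundary-layer-height derivation,
#' quality filtering, lateral-wind-speed prediction for records lacking it,
#' half-hourly footprints accumulated into the annual climatology,
#' percentile contours, footprint-weighted cover fractions and dominant
#' type, directional semivariograms with the spherical fit, sensor location
#' bias against the 80% contour and against square windows, and the
#' three-level classification. All randomness derives from `config$seed`,
#' so two runs with the same configuration produce identical outputs.
#'
#' When `out_dir` is given, the stage tables are written as CSV (contours in
#' the wide `fp50_x`/`fp50_y` dialect, areas in m^2 and km^2, cover
#' percentages, variogram parameters per direction, the SLB window table and
#' the classification) together with the land-cover and NDVI rasters as
#' ASCII grids, the met series as a FLUXNET-style CSV, and a plain-text run
#' manifest (package version, seed, filter counts).
#'
#' @param config a [scene_config()].
#' @param meta optional [site_meta()]; defaults to a tower built from
#'   `config$tower` at 56 N.
#' @param grid footprint [grid_spec()]; defaults to the NDVI resolution over
#'   the scene extent so all layers share one frame.
#' @param out_dir optional output directory (created if needed).
#' @param n_training rows of lateral-wind-speed training data.
#' @param verbose emit one message per stage.
#' @return a `fluxrep_run` list with every intermediate and final object.
#' @export
run_pipeline <- function(config, meta = NULL, grid = NULL, out_dir = NULL,
                         n_training = 4000L, verbose = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  say <- function(...) if (verbose) inform(sprintf(...))
  meta <- meta %||% site_meta(
    site_id = "SYN-001", igbp = config$tower$igbp, lat = 56, lon = 10,
    zm = config$tower$zm, hc = config$tower$hc
  )
  grid <- grid %||% grid_spec(cell = config$cell_ndvi,
                              half_width = config$half_width)

  say("scene: generating met series, land cover and NDVI (seed %d)",
      config$seed)
  met <- gen_met_series(config)
  landcover <- gen_landcover_raster(config)
  ndvi_scene <- gen_ndvi_field(config)
  # a second, cloud-contaminated scene exercises the composite filter
  ndvi <- annual_composite(list(ndvi_scene, ndvi_scene), c(0, 80))

  say("micromet: filtering %d half-hours", nrow(met))
  met <- estimate_pblh(met, lat = meta$lat)
  kept <- qc_filter(met, meta)
  report <- filter_report(kept)
  say("micromet: kept %d / %d records (stability %d, height low %d, high %d)",
      report$n_kept, report$n_input, report$n_rejected_stability,
      report$n_rejected_height_low, report$n_rejected_height_high)

  say("sigma_v: training predictor on %d synthetic rows", n_training)
  training <- gen_sigma_v_training(config, n = n_training)
  sv_model <- fit_sigma_v(training, folds = 5L, seed = config$seed)
  kept <- predict_sigma_v(sv_model, kept, meta)

  say("footprint: accumulating %d half-hourly footprints on a %d m grid",
      nrow(kept), grid$cell)
  n <- as.integer(round(2 * grid$half_width / grid$cell))
  total <- matrix(0, n, n)
  for (ii in seq_len(nrow(kept))) {
    fp <- halfhour_footprint(kept[ii, ], meta, grid)
    total <- total + fp$values
  }
  acfc <- flux_raster(total / sum(total), grid$cell, "acfc")
  acfc$n_contributing <- nrow(kept)

  say("climatology: extracting contours")
  contours <- extract_contours(acfc)

  say("landcover: footprint-weighted cover fractions")
  igbp <- aggregate_to_igbp(landcover)
  cover <- weighted_cover(acfc, contours, igbp)
  dominant <- resolve_dominant(cover, meta$igbp)

  say("heterogeneity: directional semivariograms and spherical fit")
  vgms <- map(names(variogram_directions), function(d) {
    directional_semivariogram(ndvi, acfc, contours, direction = d)
  })
  names(vgms) <- names(variogram_directions)
  omni <- omnidirectional_semivariogram(vgms)
  fit <- fit_spherical(omni)
  dir_fits <- map(vgms, fit_spherical)

  say("representativeness: sensor location bias and classification")
  ndvi_fp <- footprint_weighted_ndvi(ndvi, acfc, contours)
  ndvi_t <- target_mean_ndvi(ndvi, contours)
  slb <- sensor_location_bias(ndvi_fp, ndvi_t)
  windows <- window_profile(ndvi, ndvi_fp)
  classification <- classify_site(
    dominant$dominant_pct, fit$nugget_sill_ratio, slb$abs_slb
  )

  run <- structure(
    list(
      config = config, meta = meta, grid = grid, met = met,
      filter_report = report, sigma_v_model = sv_model,
      records = kept, acfc = acfc, contours = contours,
      landcover = landcover, igbp = igbp, ndvi = ndvi,
      cover = cover, dominant = dominant,
      variograms = vgms, omni = omni, spherical_fit = fit,
      directional_fits = dir_fits,
      slb = slb, windows = windows, classification = classification
    ),
    class = "fluxrep_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.fluxrep_run <- function(x, ...) {
  cat(sprintf("<fluxrep_run> site %s, %d half-hours accumulated\n",
              x$meta$site_id, x$acfc$n_contributing))
  cat(sprintf("  dominant cover: %s %.1f%% (match: %s)\n",
              x$dominant$dominant_abbrev, x$dominant$dominant_pct,
              x$dominant$match))
  cat(sprintf("  omnidirectional nugget/sill: %.1f%%\n",
              x$spherical_fit$nugget_sill_ratio))
  cat(sprintf("  |SLB| vs 80%% contour: %.4f\n", x$slb$abs_slb))
  cat(sprintf("  classification (Rp, Rs, Rb): %d, %d, %d\n",
              x$classification$rp, x$classification$rs, x$classification$rb))
  invisible(x)
}

variogram_param_table <- function(run) {
  fits <- c(run$directional_fits, list(omni = run$spherical_fit))
  purrr::imap(fits, function(f, d) {
    tibble(direction = d, nugget = f$nugget, sill = f$sill,
           range_m = f$range_m)
  }) |>
    purrr::list_rbind() |>
    mutate(omni_nugget_sill_ratio_pct = run$spherical_fit$nugget_sill_ratio)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_fluxnet_csv(run$met, p("met_halfhourly.csv"))
  write_ascii_grid(run$landcover, p("landcover.asc"))
  write_ascii_grid(run$ndvi, p("ndvi_composite.asc"))
  readr::write_csv(contour_table(run$contours), p("acfcc_contours.csv"))
  readr::write_csv(run$contours$summary, p("acfcc_areas.csv"))
  readr::write_csv(run$cover, p("cover_percentages.csv"))
  readr::write_csv(variogram_param_table(run), p("variogram.csv"))
  slb_tbl <- bind_rows(
    run$slb |> mutate(i = NA_integer_, side_m = NA_real_,
                      target = "acfcc80") |>
      rename(target_mean = "ndvi_target"),
    run$windows |> mutate(ndvi_fp = run$slb$ndvi_fp, target = "window")
  ) |>
    select("target", "i", "side_m", "target_mean", "ndvi_fp",
           "slb", "abs_slb")
  readr::write_csv(slb_tbl, p("slb.csv"))
  readr::write_csv(
    bind_cols(tibble(site_id = run$meta$site_id), run$classification) |>
      rename(Rp = "rp", Rs = "rs", Rb = "rb"),
    p("classification.csv")
  )
  manifest <- c(
    sprintf("fluxrep version: %s", as.character(packageVersion("fluxrep"))),
    sprintf("seed: %d", run$config$seed),
    sprintf("site: %s", run$meta$site_id),
    sprintf("grid: %g m cells, half-width %g m",
            run$grid$cell, run$grid$half_width),
    sprintf("n_input: %d", run$filter_report$n_input),
    sprintf("n_kept: %d", run$filter_report$n_kept),
    sprintf("n_rejected_stability: %d",
            run$filter_report$n_rejected_stability),
    sprintf("n_rejected_height_low: %d",
            run$filter_report$n_rejected_height_low),
    sprintf("n_rejected_height_high: %d",
            run$filter_report$n_rejected_height_high),
    sprintf("sigma_v cv_r2: %.4f", run$sigma_v_model$cv_r2),
    sprintf("sigma_v cv_mae: %.4f", run$sigma_v_model$cv_mae)
  )
  writeLines(manifest, p("manifest.txt"))
  invisible(out_dir)
}
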