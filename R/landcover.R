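#' GLC-to-IGBP aggregation table
#'
#' The code-for-code recode from the 30 m fine-classification land-cover
#' product onto IGBP classes, including the fractional-cover subclasses
#' (open/closed forest variants, sparse vegetation) and the filled value.
#' Water bodies carry ID 18 and "Unclassified" ID 17 in this scheme.
#'
#' @return tibble with `glc_code`, `glc_name`, `igbp_code`, `igbp_name`.
#' @export
glc_igbp_map <- function() {
  tribble(
    ~glc_code, ~glc_name, ~igbp_code, ~igbp_name,
    10L, "Rainfed cropland", 12L, "Croplands",
    11L, "Herbaceous cover", 12L, "Croplands",
    12L, "Tree or shrub cover (Orchard)", 12L, "Croplands",
    20L, "Irrigated cropland", 12L, "Croplands",
    50L, "Evergreen broadleaved forest", 2L, "Evergreen Broadleaf Forest",
    60L, "Deciduous broadleaved forest", 4L, "Deciduous Broadleaf Forest",
    61L, "Open deciduous broadleaved forest", 4L, "Deciduous Broadleaf Forest",
    62L, "Closed deciduous broadleaved forest", 4L, "Deciduous Broadleaf Forest",
    70L, "Evergreen needle-leaved forest", 1L, "Evergreen Needleleaf Forest",
    71L, "Open evergreen needle-leaved forest", 1L, "Evergreen Needleleaf Forest",
    72L, "Closed evergreen needle-leaved forest", 1L, "Evergreen Needleleaf Forest",
    80L, "Deciduous needle-leaved forest", 3L, "Deciduous Needleleaf Forest",
    81L, "Open deciduous needle-leaved forest", 3L, "Deciduous Needleleaf Forest",
    82L, "Closed deciduous needle-leaved forest", 3L, "Deciduous Needleleaf Forest",
    90L, "Mixed leaf forest", 5L, "Mixed Forest",
    120L, "Shrubland", 7L, "Open Shrublands",
    121L, "Evergreen shrubland", 7L, "Open Shrublands",
    122L, "Deciduous shrubland", 7L, "Open Shrublands",
    130L, "Grassland", 10L, "Grasslands",
    140L, "Lichens and mosses", 16L, "Barren or Sparsely Vegetated",
    150L, "Sparse vegetation", 16L, "Barren or Sparsely Vegetated",
    152L, "Sparse shrubland", 16L, "Barren or Sparsely Vegetated",
    153L, "Sparse herbaceous", 16L, "Barren or Sparsely Vegetated",
    180L, "Wetlands", 11L, "Permanent Wetlands",
    190L, "Impervious", 13L, "Urban and Built-Up",
    200L, "Bare areas", 16L, "Barren or Sparsely Vegetated",
    201L, "Consolidated bare areas", 16L, "Barren or Sparsely Vegetated",
    202L, "Unconsolidated bare areas", 16L, "Barren or Sparsely Vegetated",
    210L, "Waterbody", 18L, "Water Bodies",
    220L, "Permanent ice and snow", 15L, "Permanent Snow and Ice",
    250L, "Filled value", 17L, "Unclassified"
  )
}

#' IGBP class labels
#'
#' @return tibble with `igbp_code`, `abbrev`, `igbp_name` (numbering as in
#'   [glc_igbp_map()]).
#' @export
igbp_classes <- function() {
  tribble(
    ~igbp_code, ~abbrev, ~igbp_name,
    1L, "ENF", "Evergreen Needleleaf Forest",
    2L, "EBF", "Evergreen Broadleaf Forest",
    3L, "DNF", "Deciduous Needleleaf Forest",
    4L, "DBF", "Deciduous Broadleaf Forest",
    5L, "MF", "Mixed Forest",
    6L, "CSH", "Closed Shrublands",
    7L, "OSH", "Open Shrublands",
    8L, "WSA", "Woody Savannas",
    9L, "SAV", "Savannas",
    10L, "GRA", "Grasslands",
    11L, "WET", "Permanent Wetlands",
    12L, "CRO", "Croplands",
    13L, "URB", "Urban and Built-Up",
    14L, "CVM", "Cropland/Natural Vegetation Mosaic",
    15L, "SNO", "Permanent Snow and Ice",
    16L, "BSV", "Barren or Sparsely Vegetated",
    17L, "UNC", "Unclassified",
    18L, "WAT", "Water Bodies"
  )
}

#' Dominant-type alias corrections
#'
#' The fine-classification product has no woody-savanna, savanna or
#' closed-shrubland class; at such sites the dominant aggregated type is
#' accepted as a match when it is the known stand-in (deciduous broadleaf
#' forest for WSA and CSH, evergreen needleleaf forest for SAV).
#'
#' @return tibble with `site_igbp` and `dominant_igbp` codes.
#' @export
igbp_alias_map <- function() {
  tribble(
    ~site_igbp, ~dominant_igbp,
    8L, 4L,  # WSA -> DBF
    9L, 1L,  # SAV -> ENF
    6L, 4L   # CSH -> DBF
  )
}

#' Aggregate a fine-classification raster to IGBP classes
#'
#' Code-for-code recode per the aggregation table. Unmapped codes raise an
#' error listing the offending codes; `NA` cells pass through.
#'
#' @param raster a categorical `flux_raster` of GLC-style codes.
#' @param mapping recode table as from [glc_igbp_map()].
#' @return a `flux_raster` (subclass `igbp_raster`) of IGBP codes.
#' @export
aggregate_to_igbp <- function(raster, mapping = glc_igbp_map()) {
  codes <- as.vector(raster$values)
  known <- mapping$glc_code
  bad <- setdiff(unique(codes[!is.na(codes)]), known)
  if (length(bad)) {
    abort(paste0("unmapped land-cover code(s): ",
                 paste(sort(bad), collapse = ", ")))
  }
  lut <- setNames(mapping$igbp_code, mapping$glc_code)
  out <- raster
  recoded <- rep(NA_real_, length(codes))
  ok <- !is.na(codes)
  recoded[ok] <- lut[as.character(codes[ok])]
  out$values <- matrix(recoded, nrow(raster$values), ncol(raster$values))
  class(out) <- c("igbp_raster", "flux_raster")
  out
}

#' Footprint-weighted land-cover percentages
#'
#' Samples the categorical raster (nearest neighbour) at the climatology
#' cell centres inside the chosen contour mask and sums the footprint
#' weights per class: `pct(c) = 100 * sum(w | class c) / sum(w)`. The result
#' is invariant to any positive rescaling of the weights.
#'
#' @param acfc an [accumulate_footprints()] climatology.
#' @param contours the matching [extract_contours()] result.
#' @param igbp an [aggregate_to_igbp()] raster.
#' @param level contour level whose mask defines the source area.
#' @return tibble with `igbp_code`, `abbrev`, `igbp_name`, `pct`, sorted by
#'   decreasing percentage.
#' @export
weighted_cover <- function(acfc, contours, igbp, level = 80) {
  mask <- contours$masks[[as.character(level)]]
  if (is.null(mask)) abort(sprintf("no %s%% contour in `contours`.", level))
  if (!any(mask)) abort("empty contour mask.")
  xy <- raster_xy(acfc)
  w <- acfc$values[mask]
  cls <- raster_sample(igbp, xy$x[mask], xy$y[mask])
  keep <- !is.na(cls)
  if (!any(keep)) abort("contour mask falls entirely on nodata cells.")
  tibble(igbp_code = as.integer(cls[keep]), w = w[keep]) |>
    group_by(.data$igbp_code) |>
    summarise(pct = 100 * sum(.data$w), .groups = "drop") |>
    mutate(pct = .data$pct / sum(.data$pct) * 100) |>
    left_join(igbp_classes(), by = "igbp_code") |>
    select("igbp_code", "abbrev", "igbp_name", "pct") |>
    arrange(desc(.data$pct), .data$igbp_code)
}

#' Dominant cover type and site match status
#'
#' The dominant class is the cover-percentage argmax (ties broken towards
#' the smaller IGBP code, with a message). The site matches when the
#' dominant class equals the site's IGBP class directly or through the
#' alias corrections for classes absent from the fine-classification
#' product. Mismatching sites are flagged, not dropped.
#'
#' @param cover a [weighted_cover()] table.
#' @param site_igbp the site's IGBP code.
#' @param alias_map alias table as from [igbp_alias_map()].
#' @return one-row tibble: `dominant_code`, `dominant_abbrev`,
#'   `dominant_pct`, `site_igbp`, `match`, `alias_applied`.
#' @export
resolve_dominant <- function(cover, site_igbp, alias_map = igbp_alias_map()) {
  top <- cover |> arrange(desc(.data$pct), .data$igbp_code)
  if (nrow(top) > 1 && top$pct[1] == top$pct[2]) {
    inform(sprintf(
      "dominant-type tie at %.3f%%; keeping the smaller IGBP code %d.",
      top$pct[1], top$igbp_code[1]
    ))
  }
  dom <- top[1, ]
  alias <- any(alias_map$site_igbp == site_igbp &
                 alias_map$dominant_igbp == dom$igbp_code)
  tibble(
    dominant_code = dom$igbp_code,
    dominant_abbrev = dom$abbrev,
    dominant_pct = dom$pct,
    site_igbp = as.integer(site_igbp),
    match = dom$igbp_code == site_igbp || alias,
    alias_applied = alias && dom$igbp_code != site_igbp
  )
}
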