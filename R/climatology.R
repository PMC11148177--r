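#' Accumulate half-hourly footprints into a cumulative climatology
#'
#' Sums footprint grids cell-by-cell and renormalizes so the weights sum to
#' one over the domain. The operation is order-independent and idempotent
#' under duplication of identical footprints. Applied to a year of accepted
#' half-hours this yields the annual cumulative footprint climatology;
#' applied to time slices it yields monthly or seasonal climatologies.
#'
#' @param footprints list of `footprint_grid` rasters on identical grids.
#' @return a `flux_raster` of subclass `acfc` whose values sum to 1, with an
#'   `n_contributing` field.
#' @export
accumulate_footprints <- function(footprints) {
  if (length(footprints) < 1L) abort("need at least one footprint.")
  cells <- vapply(footprints, function(f) ncol(f$values), 1L)
  sizes <- vapply(footprints, function(f) f$cell, 1)
  if (length(unique(cells)) != 1L || length(unique(sizes)) != 1L) {
    abort("all footprints must share the same grid specification.")
  }
  total <- reduce(map(footprints, "values"), `+`)
  s <- sum(total)
  if (s <= 0) abort("accumulated weights sum to zero.")
  out <- flux_raster(total / s, sizes[1], c("acfc"))
  out$n_contributing <- length(footprints)
  out
}

# order of cells by decreasing weight with deterministic tie-break
# (weight desc, then row, then column)
acfc_cell_order <- function(values) {
  n <- nrow(values)
  idx <- seq_along(values)
  row <- (idx - 1L) %% n + 1L
  col <- (idx - 1L) %/% n + 1L
  order(-as.vector(values), row, col)
}

mask_boundary <- function(mask) {
  n <- nrow(mask)
  pad <- matrix(FALSE, n + 2L, n + 2L)
  pad[2:(n + 1), 2:(n + 1)] <- mask
  inner <- pad[2:(n + 1), 2:(n + 1)] &
    !(pad[1:n, 2:(n + 1)] & pad[3:(n + 2), 2:(n + 1)] &
        pad[2:(n + 1), 1:n] & pad[2:(n + 1), 3:(n + 2)])
  inner
}

#' Geometry of a source-area mask
#'
#' Area (cell count times cell area), fetch (maximum distance from the tower
#' to a boundary cell centre) and the symmetry index `A / (pi * fetch^2)` of
#' a logical cell mask on the tower-centred grid.
#'
#' @param mask logical matrix (north-up, tower at the centre).
#' @param cell cell side in metres.
#' @return one-row tibble with `n_cells`, `area_m2`, `fetch_m`, `si`.
#' @export
mask_metrics <- function(mask, cell) {
  n <- nrow(mask)
  if (!any(mask)) abort("empty mask.")
  bnd <- mask_boundary(mask)
  xs <- seq(-n / 2 * cell + cell / 2, n / 2 * cell - cell / 2, by = cell)
  ys <- rev(xs)
  idx <- which(bnd, arr.ind = TRUE)
  d <- sqrt(xs[idx[, 2]]^2 + ys[idx[, 1]]^2)
  fetch <- max(d)
  if (fetch <= 0) {
    warn("degenerate single-cell contour; using the cell scale as fetch.")
    fetch <- cell / 2
  }
  area <- sum(mask) * cell^2
  tibble(
    n_cells = sum(mask), area_m2 = area, fetch_m = fetch,
    si = symmetry_index(area, fetch)
  )
}

#' Symmetry index of a source-area contour
#'
#' `SI = A / (pi * fetch^2)`: the enclosed area relative to the disc swept by
#' the fetch. A circle centred on the tower has SI = 1; elongated or
#' one-sided source areas fall below it.
#'
#' @param area enclosed area (m^2).
#' @param fetch maximum tower-to-boundary distance (m).
#' @return dimensionless index.
#' @export
symmetry_index <- function(area, fetch) {
  area / (pi * fetch^2)
}

boundary_polylines <- function(mask, cell) {
  n <- nrow(mask)
  xs <- seq(-n / 2 * cell + cell / 2, n / 2 * cell - cell / 2, by = cell)
  # contourLines takes z[i, j] with x along i: pass the transposed,
  # row-reversed matrix so that i follows east and j north
  z <- t(mask[n:1, , drop = FALSE]) * 1
  cl <- contourLines(x = xs, y = xs, z = z, levels = 0.5)
  if (!length(cl)) {
    return(tibble(piece = integer(), x = numeric(), y = numeric()))
  }
  purrr::imap(cl, function(p, i) {
    tibble(piece = i, x = p$x, y = p$y)
  }) |> purrr::list_rbind()
}

#' Extract percentile contours from a footprint climatology
#'
#' For each level `r` the enclosed cell set is the smallest set of
#' highest-weight cells whose summed weight reaches `r/100` (ties broken by
#' weight, then row, then column), so the sets are nested across levels and
#' invariant to rescaling the weights. The boundary polyline is traced by
#' marching squares on the cell mask and is cosmetic; area, fetch and the
#' symmetry index are computed from the cell set itself.
#'
#' @param acfc an [accumulate_footprints()] climatology.
#' @param levels percentile levels in (0, 100).
#' @return a `contour_set`: list with `masks` (named list of logical
#'   matrices), `summary` (tibble: level, n_cells, area_m2, area_km2,
#'   fetch_m, si), `boundaries` (tibble: level, piece, x, y), `cell`.
#' @export
extract_contours <- function(acfc, levels = c(50, 60, 70, 80)) {
  stopifnot(inherits(acfc, "flux_raster"))
  if (any(levels <= 0 | levels >= 100)) {
    abort("contour levels must lie strictly between 0 and 100.")
  }
  v <- acfc$values / sum(acfc$values)
  ord <- acfc_cell_order(v)
  cum <- cumsum(as.vector(v)[ord])
  levels <- sort(levels)
  masks <- list()
  summaries <- list()
  bounds <- list()
  for (r in levels) {
    k <- min(which(cum >= r / 100))
    mask <- matrix(FALSE, nrow(v), ncol(v))
    mask[ord[seq_len(k)]] <- TRUE
    key <- as.character(r)
    masks[[key]] <- mask
    summaries[[key]] <- mask_metrics(mask, acfc$cell) |>
      mutate(level = r, .before = 1)
    bounds[[key]] <- boundary_polylines(mask, acfc$cell) |>
      mutate(level = r, .before = 1)
  }
  summary <- purrr::list_rbind(summaries) |>
    mutate(area_km2 = .data$area_m2 / 1e6, .after = "area_m2")
  structure(
    list(
      masks = masks, summary = summary,
      boundaries = purrr::list_rbind(bounds), cell = acfc$cell
    ),
    class = "contour_set"
  )
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set>\n")
  print(x$summary)
  invisible(x)
}

#' Export contour polylines in the wide x/y column dialect
#'
#' One column pair per level (`fp50_x`, `fp50_y`, ..., `fp80_x`, `fp80_y`),
#' coordinates in metres from the tower; shorter contours are padded with
#' `NA`.
#'
#' @param contours a [extract_contours()] result.
#' @return wide tibble.
#' @export
contour_table <- function(contours) {
  pieces <- contours$boundaries |>
    group_by(.data$level) |>
    group_split()
  cols <- list()
  for (p in pieces) {
    lv <- p$level[1]
    cols[[sprintf("fp%d_x", lv)]] <- p$x
    cols[[sprintf("fp%d_y", lv)]] <- p$y
  }
  len <- max(vapply(cols, length, 1L))
  as_tibble(map(cols, ~ c(.x, rep(NA_real_, len - length(.x)))))
}
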