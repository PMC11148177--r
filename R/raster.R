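#' Tower-centred metric rasters
#'
#' All gridded objects in fluxrep live on a square, tower-centred metric grid:
#' the tower sits at the origin, x grows to the east and y to the north, and
#' the grid spans `[-half_width, half_width]` in both directions with square
#' cells of side `cell` metres. Values are stored as a matrix whose first row
#' is the northernmost band of cells (north-up orientation, as in any image
#' raster).
#'
#' @param values square numeric (or integer) matrix, north-up.
#' @param cell cell side in metres.
#' @param subclass optional extra S3 class (e.g. `"footprint_grid"`).
#' @return A `flux_raster` object: list with `values`, `cell`, `half_width`.
#' @export
flux_raster <- function(values, cell, subclass = character()) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("`values` must be a square matrix.")
  }
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0) {
    abort("`cell` must be a single positive number.")
  }
  structure(
    list(values = values, cell = cell, half_width = ncol(values) * cell / 2),
    class = c(subclass, "flux_raster")
  )
}

#' @export
print.flux_raster <- function(x, ...) {
  cat(sprintf(
    "<%s> %d x %d cells, %g m resolution, half-width %g m\n",
    class(x)[1], nrow(x$values), ncol(x$values), x$cell, x$half_width
  ))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%g, %g]\n", min(v), max(v)))
  }
  invisible(x)
}

#' @export
dim.flux_raster <- function(x) dim(x$values)

# cell-centre coordinates; x ascending (west -> east), y for rows
# descending (north -> south) so that values[1, 1] is the NW corner
raster_x <- function(r) {
  seq(-r$half_width + r$cell / 2, r$half_width - r$cell / 2, by = r$cell)
}

raster_y <- function(r) {
  rev(seq(-r$half_width + r$cell / 2, r$half_width - r$cell / 2, by = r$cell))
}

#' Coordinate grids of a raster
#'
#' Returns matrices of the cell-centre x (east) and y (north) coordinates,
#' conformable with `r$values`.
#' @param r a [flux_raster()].
#' @return list with matrices `x` and `y` in metres from the tower.
#' @keywords internal
raster_xy <- function(r) {
  n <- ncol(r$values)
  xs <- raster_x(r)
  ys <- raster_y(r)
  list(
    x = matrix(xs, nrow = n, ncol = n, byrow = TRUE),
    y = matrix(ys, nrow = n, ncol = n)
  )
}

#' Nearest-neighbour sampling of a raster
#'
#' Looks up the value of the cell containing each `(x, y)` point. Points
#' outside the raster extent return `NA`. This is the co-registration rule
#' used throughout the package: grids of different resolution are related by
#' sampling the coarser raster at the finer grid's cell centres.
#'
#' @param r a [flux_raster()].
#' @param x,y point coordinates in metres from the tower (east, north).
#' @return vector of sampled values.
#' @export
raster_sample <- function(r, x, y) {
  n <- ncol(r$values)
  j <- ceiling((x + r$half_width) / r$cell)
  i <- ceiling((r$half_width - y) / r$cell)
  # points exactly on the west/north edge fall into the first cell
  j[x == -r$half_width] <- 1L
  i[y == r$half_width] <- 1L
  ok <- !is.na(i) & !is.na(j) & i >= 1 & i <= n & j >= 1 & j <= n
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(i[ok], j[ok])]
  out
}

#' @export
as_tibble.flux_raster <- function(x, ...) {
  xy <- raster_xy(x)
  vals <- as.vector(x$values)
  tibble(x = as.vector(xy$x), y = as.vector(xy$y), value = vals)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text headered grid (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value followed by rows from north to south), readable by any GIS.
#' Coordinates are metres relative to the tower.
#'
#' @param r a [flux_raster()].
#' @param path file path.
#' @param nodata value written in place of `NA`.
#' @return `path`, invisibly (writer); a `flux_raster` (reader).
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  vals <- r$values
  vals[is.na(vals)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(vals)),
    sprintf("nrows %d", nrow(vals)),
    sprintf("xllcorner %g", -r$half_width),
    sprintf("yllcorner %g", -r$half_width),
    sprintf("cellsize %g", r$cell),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(vals, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param subclass extra S3 class for the object read back.
#' @export
read_ascii_grid <- function(path, subclass = character()) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- tolower(keys)
  n <- as.integer(vals[["ncols"]])
  body <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  body[body == vals[["nodata_value"]]] <- NA
  stopifnot(nrow(body) == vals[["nrows"]], ncol(body) == n)
  flux_raster(body, cell = vals[["cellsize"]], subclass = subclass)
}
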