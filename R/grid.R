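#' Define a regular geographic analysis grid
#'
#' Builds the regular lon/lat lattice on which tracking locations and
#' environmental layers are overlaid. Cells are indexed row-major from the
#' north-west corner: cell `(r, c)` (1-based) covers the half-open box
#' `[lon_min + (c-1)*cell, lon_min + c*cell)` in longitude and
#' `(lat_max - r*cell, lat_max - (r-1)*cell]` in latitude, so every point
#' maps to at most one cell.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid bounds in decimal degrees.
#' @param cell_deg Cell size in degrees (default 0.04, roughly a 4 km^2 cell
#'   at subantarctic latitudes).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- make_grid(-110, -10, -75, -40, 0.04)
#' g$n_cols  # 2500
#' g$n_rows  # 875
#' @export
make_grid <- function(lon_min, lon_max, lat_min, lat_max, cell_deg = 0.04) {
  if (!is.numeric(cell_deg) || length(cell_deg) != 1L || cell_deg <= 0)
    stop("cell_deg must be a single positive number")
  if (lon_min >= lon_max || lat_min >= lat_max)
    stop("inverted or empty bounds: require lon_min < lon_max and lat_min < lat_max")
  n_cols <- as.integer(round((lon_max - lon_min) / cell_deg))
  n_rows <- as.integer(round((lat_max - lat_min) / cell_deg))
  if (n_cols < 1L || n_rows < 1L)
    stop("grid has no cells; bounds are smaller than one cell")
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         cell_deg = cell_deg, n_cols = n_cols, n_rows = n_rows),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols at %g deg (%g..%g lon, %g..%g lat)\n",
              x$n_rows, x$n_cols, x$cell_deg,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A `grid_spec`.
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Map points to grid cell ids
#'
#' Cell ids are row-major from the north-west corner
#' (`id = (r-1)*n_cols + c`). Points on an interior cell edge belong to the
#' cell for which the coordinate is the closed (half-open) bound: the eastern
#' cell for a longitude edge, the southern cell for a latitude edge. Points
#' outside the grid map to `NA`.
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Numeric vectors of coordinates (degrees), recycled to a
#'   common length.
#' @return Integer vector of cell ids (`NA` outside the grid).
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  cc <- floor((lon - grid$lon_min) / grid$cell_deg)        # 0-based col
  rr <- floor((grid$lat_max - lat) / grid$cell_deg)        # 0-based row
  ok <- !is.na(cc) & !is.na(rr) &
    cc >= 0 & cc < grid$n_cols & rr >= 0 & rr < grid$n_rows
  id <- rep(NA_integer_, n)
  id[ok] <- as.integer(rr[ok] * grid$n_cols + cc[ok] + 1)
  id
}

#' Row/column indices of cells
#' @param grid A `grid_spec`.
#' @param cells Integer cell ids.
#' @return Data frame with 1-based `row` (from the north) and `col` (from the
#'   west).
#' @export
cell_to_rowcol <- function(grid, cells) {
  stopifnot(all(cells >= 1L & cells <= n_cells(grid), na.rm = TRUE))
  data.frame(row = (cells - 1L) %/% grid$n_cols + 1L,
             col = (cells - 1L) %% grid$n_cols + 1L)
}

#' Cell centre coordinates
#' @param grid A `grid_spec`.
#' @param cells Integer cell ids.
#' @return Data frame with `lon`, `lat` of cell centres.
#' @export
cell_center <- function(grid, cells) {
  rc <- cell_to_rowcol(grid, cells)
  data.frame(lon = grid$lon_min + (rc$col - 0.5) * grid$cell_deg,
             lat = grid$lat_max - (rc$row - 0.5) * grid$cell_deg)
}

# Row-major cell ids -> linear index into an n_rows x n_cols R matrix
# (R matrices are column-major, so this conversion is needed everywhere a
# layer matrix is subset by cell id).
mat_index <- function(grid, cells) {
  rc <- cell_to_rowcol(grid, cells)
  (rc$col - 1L) * grid$n_rows + rc$row
}

#' A minimal in-memory georeferenced raster
#'
#' Holds a matrix of pixel values with geographic bounds; row 1 is the
#' northernmost pixel row. Used as the source object for [aggregate_to_grid()]
#' and produced by [read_ascii_grid()].
#'
#' @param values Numeric matrix (rows north to south).
#' @param lon_min,lon_max,lat_min,lat_max Bounds in degrees.
#' @return An object of class `simple_raster`.
#' @export
simple_raster <- function(values, lon_min, lon_max, lat_min, lat_max) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (lon_min >= lon_max || lat_min >= lat_max) stop("inverted raster bounds")
  structure(list(values = values,
                 lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max),
            class = "simple_raster")
}

#' Aggregate a finer raster onto the analysis grid
#'
#' Each grid cell receives the arithmetic mean of the source pixels whose
#' centres fall inside it; missing source pixels are skipped, and a cell
#' covered only by missing pixels (or by none) is missing.
#'
#' @param raster A [simple_raster()].
#' @param grid A `grid_spec`.
#' @return A numeric layer matrix (`n_rows x n_cols`) on the grid.
#' @export
aggregate_to_grid <- function(raster, grid) {
  stopifnot(inherits(raster, "simple_raster"), inherits(grid, "grid_spec"))
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  dx <- (raster$lon_max - raster$lon_min) / nc
  dy <- (raster$lat_max - raster$lat_min) / nr
  lon_c <- raster$lon_min + (seq_len(nc) - 0.5) * dx
  lat_c <- raster$lat_max - (seq_len(nr) - 0.5) * dy
  ids <- cell_from_lonlat(grid,
                          lon = rep(lon_c, each = nr),
                          lat = rep(lat_c, times = nc))
  inside <- !is.na(ids)
  if (!any(inside)) stop("raster lies wholly outside the grid")
  vals <- as.vector(v)[inside]
  ids <- ids[inside]
  sums <- tapply(vals, ids, function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  })
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[mat_index(grid, as.integer(names(sums)))] <- as.numeric(sums)
  out
}
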