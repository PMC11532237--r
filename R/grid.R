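#' Define a regular longitude-latitude grid
#'
#' All gridded quantities in the package (soil moisture, emissions, modeled
#' PM2.5, population) live on one shared regular grid. Fields are stored in
#' tidy long format: one row per cell (and per day for time-varying fields)
#' with `lat` and `lon` giving the cell centre.
#'
#' @param nlon,nlat Number of cells along longitude and latitude.
#' @param lon_min,lon_max,lat_min,lat_max Outer grid bounds in degrees.
#' @return A `grid_spec` object: cell-centre vectors plus cell sizes.
#' @examples
#' g <- grid_spec(nlon = 10, nlat = 10)
#' grid_cells(g)
#' @export
grid_spec <- function(nlon = 10, nlat = 10,
                      lon_min = 113, lon_max = 115,
                      lat_min = -3.5, lat_max = -1.5) {
  if (nlon < 1 || nlat < 1) {
    stop("degenerate grid: nlon and nlat must be >= 1", call. = FALSE)
  }
  if (lon_max <= lon_min || lat_max <= lat_min) {
    stop("degenerate grid: bounds must satisfy max > min", call. = FALSE)
  }
  res_lon <- (lon_max - lon_min) / nlon
  res_lat <- (lat_max - lat_min) / nlat
  structure(
    list(
      lon = lon_min + res_lon * (seq_len(nlon) - 0.5),
      lat = lat_min + res_lat * (seq_len(nlat) - 0.5),
      lon_bounds = c(lon_min, lon_max),
      lat_bounds = c(lat_min, lat_max),
      res_lon = res_lon,
      res_lat = res_lat
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
    length(x$lon), length(x$lat),
    x$lon_bounds[1], x$lon_bounds[2], x$lat_bounds[1], x$lat_bounds[2]
  ))
  invisible(x)
}

#' Enumerate grid cells as a tibble
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `lon`, `lat` (cell centres).
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  tidyr::expand_grid(lat = grid$lat, lon = grid$lon)
}

# Index of the cell containing each coordinate along one axis.
# Points exactly on an interior cell edge snap to the lower-index cell.
.axis_index <- function(x, centers, res, bounds) {
  edges <- c(bounds[1], (centers[-length(centers)] + centers[-1]) / 2, bounds[2])
  i <- findInterval(x, edges, left.open = TRUE)
  i[x == bounds[1]] <- 1L
  if (any(x < bounds[1] | x > bounds[2])) {
    stop("coordinate outside grid bounds", call. = FALSE)
  }
  i
}

#' Snap coordinates to their containing grid cell
#'
#' Returns the cell-centre coordinates of the cell containing each point.
#' Points on an interior cell edge are assigned deterministically to the
#' lower-index cell; points outside the grid bounds are an error.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors (degrees), recycled to common length.
#' @return A tibble with columns `lon`, `lat` of cell centres.
#' @export
snap_to_grid <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n)
  lat <- rep_len(lat, n)
  ilon <- .axis_index(lon, grid$lon, grid$res_lon, grid$lon_bounds)
  ilat <- .axis_index(lat, grid$lat, grid$res_lat, grid$lat_bounds)
  tibble::tibble(lon = grid$lon[ilon], lat = grid$lat[ilat])
}
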