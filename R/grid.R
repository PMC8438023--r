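#' Define the study grid
#'
#' A regular longitude/latitude grid (WGS84 decimal degrees) with a fixed
#' per-cell area. The default covers the cropped rectangle of Asia used for
#' the cobra analyses: longitude 40--150, latitude -10--50 at 0.5 degree
#' resolution, i.e. 220 x 120 = 26,400 cells. Each 0.5 degree cell is
#' treated as 60 x 60 km = 3600 km^2 with no latitude correction; pass
#' \code{latitude_correction = TRUE} for a cos(latitude)-weighted alternative
#' used only by \code{\link{area_of}}.
#'
#' Grid indexing is row-major from the northwest corner: row 1 is the
#' northernmost row, column 1 the westernmost column. Cells are half-open so
#' that every point belongs to exactly one cell: a point on a shared
#' north-south edge falls in the eastern (larger-column) cell, a point on a
#' shared east-west edge falls in the southern (larger-row) cell.
#'
#' @param lon_min,lon_max,lat_min,lat_max grid extent in decimal degrees.
#' @param resolution cell size in degrees; the extent must be an integral
#'   number of cells on both axes.
#' @param cell_area area of one cell in km^2 (constant over the grid).
#' @param land_mask optional logical matrix (\code{n_rows} x \code{n_cols});
#'   \code{TRUE} marks land cells. \code{NULL} means all cells are land.
#' @param latitude_correction if \code{TRUE}, \code{\link{area_of}} weights
#'   cells by cos(latitude of the cell center); off by default.
#' @return an object of class \code{study_grid}.
#' @examples
#' g <- study_grid()
#' g$n_rows * g$n_cols  # 26400
#' @export
study_grid <- function(lon_min = 40, lon_max = 150, lat_min = -10, lat_max = 50,
                       resolution = 0.5, cell_area = 3600, land_mask = NULL,
                       latitude_correction = FALSE) {
  stopifnot(resolution > 0, lon_max > lon_min, lat_max > lat_min)
  n_cols <- (lon_max - lon_min) / resolution
  n_rows <- (lat_max - lat_min) / resolution
  if (abs(n_cols - round(n_cols)) > 1e-8)
    stop("longitude extent ", lon_min, "..", lon_max,
         " is not an integral number of cells at resolution ", resolution)
  if (abs(n_rows - round(n_rows)) > 1e-8)
    stop("latitude extent ", lat_min, "..", lat_max,
         " is not an integral number of cells at resolution ", resolution)
  n_cols <- as.integer(round(n_cols))
  n_rows <- as.integer(round(n_rows))
  if (!is.null(land_mask)) {
    land_mask <- as.matrix(land_mask)
    stopifnot(is.logical(land_mask), nrow(land_mask) == n_rows,
              ncol(land_mask) == n_cols)
  }
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 resolution = resolution, n_cols = n_cols, n_rows = n_rows,
                 cell_area = cell_area, land_mask = land_mask,
                 latitude_correction = latitude_correction),
            class = "study_grid")
}

#' @export
print.study_grid <- function(x, ...) {
  cat("study_grid: ", x$n_rows, " rows x ", x$n_cols, " cols @ ",
      x$resolution, " deg (", x$n_rows * x$n_cols, " cells)\n", sep = "")
  cat("  lon ", x$lon_min, "..", x$lon_max, ", lat ", x$lat_min, "..",
      x$lat_max, ", cell area ", x$cell_area, " km^2\n", sep = "")
  if (!is.null(x$land_mask))
    cat("  land cells: ", sum(x$land_mask), "\n", sep = "")
  invisible(x)
}

# longitudes / latitudes of cell centers, by column / row index
#' Cell-center coordinates
#' @param grid a \code{\link{study_grid}}.
#' @return list with \code{lon} (length \code{n_cols}) and \code{lat}
#'   (length \code{n_rows}, north to south) of cell centers.
#' @export
cell_centers <- function(grid) {
  list(lon = grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution,
       lat = grid$lat_max - (seq_len(grid$n_rows) - 0.5) * grid$resolution)
}

#' Locate points on the grid
#'
#' Maps longitude/latitude points to (row, col) cell indices under the
#' half-open cell convention (edge points go to the larger index).
#'
#' @param grid a \code{\link{study_grid}}.
#' @param lon,lat numeric vectors of equal length.
#' @return data.frame with columns \code{row}, \code{col}, \code{inside};
#'   \code{row}/\code{col} are \code{NA} for points outside the extent.
#' @export
cell_of <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  eps <- 1e-9
  col <- floor((lon - grid$lon_min) / grid$resolution + eps) + 1L
  row <- floor((grid$lat_max - lat) / grid$resolution + eps) + 1L
  inside <- col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(row = row, col = col, inside = inside)
}

#' Convert a cell count to an area
#'
#' Areas follow the constant-cell-area convention (3600 km^2 per 0.5 degree
#' cell by default); with \code{latitude_correction} on the grid, counts must
#' be supplied per row instead.
#'
#' @param cell_count number of cells (scalar), or, for latitude-corrected
#'   grids, a vector of per-row counts of length \code{n_rows}.
#' @param grid a \code{\link{study_grid}}.
#' @return area in km^2.
#' @examples
#' area_of(1, study_grid())  # 3600
#' @export
area_of <- function(cell_count, grid) {
  stopifnot(all(cell_count >= 0))
  if (isTRUE(grid$latitude_correction)) {
    if (length(cell_count) != grid$n_rows)
      stop("latitude-corrected grids need per-row cell counts")
    lat <- cell_centers(grid)$lat
    return(sum(cell_count * grid$cell_area * cos(lat * pi / 180)))
  }
  sum(cell_count) * grid$cell_area
}

# blank layer on the grid geometry
grid_layer <- function(grid, fill = NA_real_) {
  matrix(fill, nrow = grid$n_rows, ncol = grid$n_cols)
}

check_geometry <- function(grid, mat, what = "layer") {
  if (!is.matrix(mat) || nrow(mat) != grid$n_rows || ncol(mat) != grid$n_cols)
    stop(what, " geometry (", nrow(mat), " x ", ncol(mat),
         ") does not match the grid (", grid$n_rows, " x ", grid$n_cols, ")")
  invisible(TRUE)
}
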