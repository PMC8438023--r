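#' Read and write grid layers as ESRI ASCII rasters
#'
#' Layers travel as plain-text ESRI ASCII grids (\code{.asc}): a six-line
#' header (\code{ncols}, \code{nrows}, \code{xllcorner}, \code{yllcorner},
#' \code{cellsize}, \code{NODATA_value}) followed by rows of values from the
#' northernmost row down. Missing cells are written as the nodata sentinel on
#' disk but are always \code{NA} in memory -- no sentinel numbers leak into
#' analyses. Values round-trip exactly (written with full double precision).
#'
#' @param mat numeric matrix, row 1 = northernmost row.
#' @param grid the \code{\link{study_grid}} giving the georeference.
#' @param path file path.
#' @param nodata sentinel used on disk for \code{NA}.
#' @return \code{read_asc}: a list with \code{data} (matrix), \code{lon_min},
#'   \code{lat_min}, \code{cellsize}. \code{write_asc}: the path, invisibly.
#' @export
write_asc <- function(mat, grid, path, nodata = -9999) {
  check_geometry(grid, mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(mat)),
               paste("nrows", nrow(mat)),
               paste("xllcorner", format(grid$lon_min, digits = 15)),
               paste("yllcorner", format(grid$lat_min, digits = 15)),
               paste("cellsize", format(grid$resolution, digits = 15)),
               paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(m[i, ], format = "g", digits = 17), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  header <- readLines(path, n = 6L)
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  vec <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  if (length(vec) != nc * nr)
    stop("expected ", nc * nr, " values in ", path, ", found ", length(vec))
  m <- matrix(vec, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(data = m, lon_min = vals[["xllcorner"]], lat_min = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]])
}

# Crop and/or block-aggregate a raw raster read onto the grid geometry.
# Finer resolutions are only accepted when `aggregate = "mean"` and the
# refinement factor is integral.
align_to_grid <- function(raw, grid, aggregate = c("error", "mean"),
                          what = "raster") {
  aggregate <- match.arg(aggregate)
  ratio <- grid$resolution / raw$cellsize
  if (abs(ratio - round(ratio)) > 1e-6 || ratio < 1 - 1e-9)
    stop(what, ": cell size ", raw$cellsize,
         " is not an integral refinement of the grid resolution ",
         grid$resolution)
  ratio <- as.integer(round(ratio))
  m <- raw$data
  if (ratio > 1L) {
    if (aggregate == "error")
      stop(what, ": resolution ", raw$cellsize, " finer than the grid; ",
           "pass aggregate = \"mean\" to block-average")
    m <- block_reduce(m, ratio, mean)
  }
  # crop to the grid extent (source may extend beyond it)
  src_lat_max <- raw$lat_min + nrow(m) * grid$resolution
  col0 <- (grid$lon_min - raw$lon_min) / grid$resolution
  row0 <- (src_lat_max - grid$lat_max) / grid$resolution
  if (abs(col0 - round(col0)) > 1e-6 || abs(row0 - round(row0)) > 1e-6)
    stop(what, ": source grid is not aligned with the study grid edges")
  col0 <- as.integer(round(col0)); row0 <- as.integer(round(row0))
  if (col0 < 0 || row0 < 0 || col0 + grid$n_cols > ncol(m) ||
      row0 + grid$n_rows > nrow(m))
    stop(what, ": source extent does not cover the study grid")
  m[row0 + seq_len(grid$n_rows), col0 + seq_len(grid$n_cols), drop = FALSE]
}

# f x f block reduction (fun = mean or sum); NA-aware for mean via na.rm
block_reduce <- function(m, f, fun) {
  nr <- nrow(m) / f; nc <- ncol(m) / f
  if (nr != round(nr) || nc != round(nc))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") are not divisible by the block factor ", f)
  # collapse rows then columns in f-blocks
  ridx <- rep(seq_len(nr), each = f)
  cidx <- rep(seq_len(nc), each = f)
  s <- rowsum(m, ridx, na.rm = FALSE)
  s <- t(rowsum(t(s), cidx, na.rm = FALSE))
  dimnames(s) <- NULL
  if (identical(fun, mean)) s / (f * f) else s
}

#' Read a bioclim climate stack
#'
#' Assembles the per-variable layers of one (scenario, GCM) pair into a
#' \code{climate_stack}. Sources are ESRI ASCII grids, either discovered in a
#' directory under the naming convention
#' \code{<scenario>_<gcm>_bio<k>.asc}, or given explicitly as a character
#' vector of paths named \code{bio<k>} (any order -- the declared names, not
#' the file order, decide which variable a file holds).
#'
#' @param source directory containing the layer files, or a named character
#'   vector of paths with names \code{"bio1"}, \code{"bio12"}, ...
#' @param scenario one of \code{"present"}, \code{"rcp26"}, \code{"rcp45"},
#'   \code{"rcp60"}, \code{"rcp85"}.
#' @param gcm GCM identifier (e.g. \code{"CCSM"}).
#' @param grid target \code{\link{study_grid}}.
#' @param vars integer bioclim indices to load (default 1:19).
#' @param aggregate what to do with finer-resolution sources:
#'   \code{"error"} (default) or \code{"mean"} (block-average).
#' @return a \code{climate_stack}: list with \code{scenario}, \code{gcm},
#'   \code{vars} and \code{layers} (named list of matrices \code{bio<k>}).
#' @export
read_climate_stack <- function(source, scenario, gcm, grid, vars = 1:19,
                               aggregate = c("error", "mean")) {
  aggregate <- match.arg(aggregate)
  scenario <- match.arg(scenario, c("present", "rcp26", "rcp45", "rcp60", "rcp85"))
  stopifnot(all(vars == round(vars)), all(vars >= 1), all(vars <= 19))
  if (length(source) == 1L && dir.exists(source)) {
    paths <- file.path(source, sprintf("%s_%s_bio%d.asc", scenario, gcm, vars))
    names(paths) <- sprintf("bio%d", vars)
  } else {
    paths <- source
    if (is.null(names(paths)) || !all(sprintf("bio%d", vars) %in% names(paths)))
      stop("explicit path vectors must be named bio<k> covering every requested index")
    paths <- paths[sprintf("bio%d", vars)]
  }
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("missing layer file(s): ", paste(missing_files, collapse = ", "))
  layers <- lapply(paths, function(p)
    align_to_grid(read_asc(p), grid, aggregate, what = basename(p)))
  climate_stack(layers, scenario, gcm, grid)
}

#' Build a climate stack from in-memory layers
#'
#' @param layers named list of matrices (\code{bio<k>}) on the grid geometry.
#' @param scenario,gcm provenance labels.
#' @param grid the \code{\link{study_grid}}.
#' @return a \code{climate_stack}.
#' @export
climate_stack <- function(layers, scenario, gcm, grid) {
  stopifnot(length(layers) > 0, !is.null(names(layers)),
            all(grepl("^bio[0-9]+$", names(layers))))
  for (nm in names(layers)) check_geometry(grid, layers[[nm]], nm)
  vars <- as.integer(sub("^bio", "", names(layers)))
  structure(list(scenario = scenario, gcm = gcm, vars = vars,
                 layers = layers, grid = grid),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat("climate_stack [", x$scenario, "/", x$gcm, "]: ",
      length(x$layers), " layers (", paste0("bio", x$vars, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Write every layer of a stack as ASCII grids
#' @param stack a \code{climate_stack}.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_climate_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, sprintf("%s_%s_%s.asc", stack$scenario, stack$gcm, nm))
    write_asc(stack$layers[[nm]], stack$grid, p)
    p
  }, "")
  invisible(paths)
}

#' Extract climate values at points
#'
#' Each point takes the value of the grid cell containing it (half-open cell
#' convention, see \code{\link{study_grid}}). Points outside the extent, and
#' points whose cell is missing on any layer, are dropped and reported.
#'
#' @param stack a \code{climate_stack}.
#' @param points data.frame with \code{lon} and \code{lat} columns.
#' @return list with \code{values} (matrix, one row per retained point,
#'   columns \code{bio<k>}), \code{kept} (row indices of \code{points}
#'   retained) and \code{dropped} (data.frame of row index + reason).
#' @export
extract_values <- function(stack, points) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  loc <- cell_of(stack$grid, points$lon, points$lat)
  n <- nrow(points)
  vals <- matrix(NA_real_, nrow = n, ncol = length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  ok <- loc$inside
  if (any(ok)) {
    idx <- cbind(loc$row[ok], loc$col[ok])
    for (j in seq_along(stack$layers))
      vals[ok, j] <- stack$layers[[j]][idx]
  }
  incomplete <- ok & apply(is.na(vals), 1L, any)
  keep <- ok & !incomplete
  reason <- character(0); where <- integer(0)
  if (any(!ok)) { where <- which(!ok); reason <- rep("outside_extent", sum(!ok)) }
  if (any(incomplete)) {
    where <- c(where, which(incomplete))
    reason <- c(reason, rep("missing_climate", sum(incomplete)))
  }
  dropped <- data.frame(index = where, reason = reason)
  dropped <- dropped[order(dropped$index), , drop = FALSE]
  rownames(dropped) <- NULL
  list(values = vals[keep, , drop = FALSE], kept = which(keep), dropped = dropped)
}
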