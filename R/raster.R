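#' Georeferenced raster grid
#'
#' Lightweight container for one covariate or score on a regular grid:
#' a numeric matrix plus the geotransform (upper-left corner origin, square
#' cell size). Coordinates are planar Cartesian in km for synthetic worlds.
#' Missing cells are stored as `NA` internally and mapped to the `nodata`
#' sentinel on disk.
#'
#' Cell coordinate convention: the center of cell `(row, col)` (1-based) is
#' `origin_x + (col - 0.5) * cell_size`,
#' `origin_y - (row - 0.5) * cell_size`; point-to-cell lookups use floor
#' division on this convention.
#'
#' @param values numeric matrix (rows index y from the top, cols index x).
#' @param origin_x,origin_y coordinate of the upper-left corner.
#' @param cell_size cell edge length in km (the analysis lattice is 1 km).
#' @param nodata sentinel written to disk for `NA` cells.
#' @param crs_tag free-text coordinate-system label.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = NULL, cell_size = 1,
                        nodata = -9999, crs_tag = "planar_km") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(origin_y)) origin_y <- nrow(values) * cell_size
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(list(values = values, origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, nodata = nodata, crs_tag = crs_tag),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cell %.3g km, origin (%.6g, %.6g), crs '%s'\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_x, x$origin_y, x$crs_tag))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%.4g, %.4g], %d NA\n",
                             min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_is_empty <- function(g) all(is.na(g$values))

#' Check that rasters are co-registered
#'
#' All co-used rasters must share shape, origin and cell size. Errors name
#' the offending pair.
#'
#' @param ... `raster_grid` objects or lists of them.
#' @param labels optional names used in error messages.
#' @return invisibly `TRUE`.
#' @export
check_coregistered <- function(..., labels = NULL) {
  grids <- list(...)
  if (length(grids) == 1L && !inherits(grids[[1L]], "raster_grid"))
    grids <- grids[[1L]]
  if (is.null(labels)) {
    labels <- names(grids)
    if (is.null(labels)) labels <- paste0("grid", seq_along(grids))
  }
  if (length(grids) < 2L) return(invisible(TRUE))
  ref <- grids[[1L]]
  for (i in seq_along(grids)[-1L]) {
    g <- grids[[i]]
    same <- identical(dim(g$values), dim(ref$values)) &&
      isTRUE(all.equal(c(g$origin_x, g$origin_y, g$cell_size),
                       c(ref$origin_x, ref$origin_y, ref$cell_size),
                       tolerance = 1e-9))
    if (!same)
      stop(sprintf("rasters '%s' and '%s' are not co-registered (shape/origin/cell size differ)",
                   labels[1L], labels[i]))
  }
  invisible(TRUE)
}

#' Cell centers of a raster grid
#' @param grid a `raster_grid`.
#' @return data.frame with row, col, x, y, value (row-major order).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(row = row, col = col,
             x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y - (row - 0.5) * grid$cell_size,
             value = as.vector(grid$values))
}

#' Locate the cell containing each point
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates.
#' @return data.frame with row, col (NA outside the grid).
#' @export
cell_at <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#' @inheritParams cell_at
#' @return numeric vector (NA outside the grid or at nodata cells).
#' @export
extract_at <- function(grid, x, y) {
  rc <- cell_at(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Extract values from every layer of a stack at point locations
#' @param stack named list of co-registered `raster_grid` layers.
#' @param x,y point coordinates.
#' @return matrix, one column per layer.
#' @export
extract_stack_at <- function(stack, x, y) {
  check_coregistered(stack)
  out <- vapply(stack, extract_at, numeric(length(x)), x = x, y = y)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(x))
  colnames(out) <- names(stack)
  out
}
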