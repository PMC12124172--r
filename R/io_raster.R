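#' Write a raster (or stack) to ESRI ASCII grid files
#'
#' Single grids are written as one `.asc` file. Multi-layer stacks are
#' written as one `.asc` per band plus a small JSON manifest
#' (`<path>` with extension `.stack.json`) recording band order, so a later
#' [read_raster()] returns the bands in the order they were written.
#'
#' @param x a `raster_grid` or a named list of co-registered grids.
#' @param path output path. For stacks, the manifest path; band files are
#'   derived from it.
#' @param digits significant digits written (default 10; determinism).
#' @return invisibly, the path(s) written.
#' @export
write_raster <- function(x, path, digits = 10) {
  if (inherits(x, "raster_grid")) {
    write_asc_one(x, path, digits)
    return(invisible(path))
  }
  stopifnot(is.list(x), length(x) >= 1L)
  check_coregistered(x)
  nms <- names(x)
  if (is.null(nms) || any(nms == "")) nms <- paste0("band", seq_along(x))
  base <- sub("\\.stack\\.json$", "", path)
  band_files <- paste0(base, "_", nms, ".asc")
  for (i in seq_along(x)) write_asc_one(x[[i]], band_files[i], digits)
  manifest_path <- paste0(base, ".stack.json")
  jsonlite::write_json(list(bands = nms, files = basename(band_files),
                            crs_tag = x[[1L]]$crs_tag),
                       manifest_path, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(manifest_path, band_files))
}

write_asc_one <- function(g, path, digits = 10) {
  stopifnot(inherits(g, "raster_grid"))
  v <- g$values
  v[is.na(v)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  # ESRI convention: xll/yll are the lower-left corner
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - nrow(v) * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata)
  ), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(formatC(v[i, ], digits = digits, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster or stack
#'
#' `path` may be a single `.asc` file, a `.stack.json` manifest written by
#' [write_raster()] (bands returned in written order), or a vector of `.asc`
#' paths. If `reference` is given, every band is checked for co-registration
#' against it and a mismatch raises an error naming both files.
#'
#' @param path file path(s).
#' @param reference optional `raster_grid` that read grids must align with.
#' @param crs_tag label attached to the grids read.
#' @return a `raster_grid`, or a named list of them for stacks/multiple paths.
#' @export
read_raster <- function(path, reference = NULL, crs_tag = "planar_km") {
  if (length(path) == 1L && grepl("\\.stack\\.json$", path)) {
    man <- jsonlite::read_json(path, simplifyVector = TRUE)
    files <- file.path(dirname(path), man$files)
    out <- lapply(files, read_asc_one,
                  crs_tag = if (!is.null(man$crs_tag)) man$crs_tag[1L] else crs_tag)
    names(out) <- man$bands
    check_read_reference(out, files, reference, path)
    return(out)
  }
  if (length(path) > 1L) {
    out <- lapply(path, read_asc_one, crs_tag = crs_tag)
    names(out) <- sub("\\.asc$", "", basename(path))
    check_read_reference(out, path, reference, path[1L])
    return(out)
  }
  g <- read_asc_one(path, crs_tag)
  check_read_reference(list(g), path, reference, path)
  g
}

check_read_reference <- function(grids, files, reference, label) {
  if (is.null(reference)) return(invisible(TRUE))
  for (i in seq_along(grids)) {
    ok <- tryCatch({
      check_coregistered(list(reference, grids[[i]]),
                         labels = c("reference", files[i]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf("raster '%s' is not co-registered with reference grid '%s'",
                   files[i], attr(reference, "source") %||% "reference"))
  }
  invisible(TRUE)
}

read_asc_one <- function(path, crs_tag = "planar_km") {
  if (!file.exists(path)) stop(sprintf("raster file '%s' does not exist", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("'%s' is not a valid ASCII grid (missing header fields)", path))
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("'%s': expected %d values, found %d", path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  g <- raster_grid(m,
                   origin_x = hdr$xllcorner %||% 0,
                   origin_y = (hdr$yllcorner %||% 0) + nr * hdr$cellsize,
                   cell_size = hdr$cellsize, nodata = nodata, crs_tag = crs_tag)
  attr(g, "source") <- path
  if (grid_is_empty(g)) attr(g, "empty") <- TRUE
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
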