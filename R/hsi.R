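#' Apply suitability mask rules to a prey-richness layer
#'
#' The habitat suitability index (HSI) keeps the prey-richness value (0-7)
#' wherever the landscape passes both masks and is 0 elsewhere: cells with
#' human modification at or above `hm_limit` (default 0.25; only relatively
#' low-modification areas are suitable) or crop cover at or above
#' `crop_limit` (default 0.10; only low-density crop areas are suitable)
#' are unsuitable. Boundary equality resolves toward unsuitable. Nodata in
#' any input propagates.
#'
#' @param richness `raster_grid` of integer prey richness (0..n_species).
#' @param human_mod `raster_grid`, values in \[0, 1\].
#' @param crop `raster_grid` of crop-cover proportion in \[0, 1\].
#' @param hm_limit,crop_limit mask thresholds in \[0, 1\].
#' @return an `hsi_grid` (a `raster_grid` with a `provenance` attribute
#'   recording the thresholds).
#' @export
apply_mask_rules <- function(richness, human_mod, crop,
                             hm_limit = 0.25, crop_limit = 0.10) {
  if (hm_limit < 0 || hm_limit > 1 || crop_limit < 0 || crop_limit > 1)
    stop("mask limits must lie in [0, 1]")
  check_coregistered(list(richness = richness, human_mod = human_mod,
                          crop = crop))
  r <- richness$values; h <- human_mod$values; cr <- crop$values
  out <- r
  out[h >= hm_limit | cr >= crop_limit] <- 0
  out[is.na(r) | is.na(h) | is.na(cr)] <- NA_real_
  g <- raster_grid(out, richness$origin_x, richness$origin_y,
                   richness$cell_size, richness$nodata, richness$crs_tag)
  attr(g, "provenance") <- list(hm_limit = hm_limit, crop_limit = crop_limit)
  class(g) <- c("hsi_grid", class(g))
  g
}

#' Scott's-rule bandwidth for a 2-D Gaussian KDE
#' @param x,y source point coordinates.
#' @return length-2 bandwidth vector (km per axis).
#' @export
scott_bandwidth <- function(x, y) {
  n <- length(x)
  h <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  h[!is.finite(h) | h <= 0] <- max(h[is.finite(h) & h > 0], 1)
  h
}

#' Evaluate a 2-D Gaussian KDE on a raster lattice
#'
#' Product Gaussian kernel; the returned surface integrates to ~1 over the
#' plane (cell mass = density x cell area).
#'
#' @param x,y source point coordinates.
#' @param bandwidth length-2 vector (km per axis).
#' @param grid `raster_grid` template defining the evaluation lattice.
#' @param weights optional nonnegative point weights.
#' @return `raster_grid` of density values.
#' @export
kde_surface <- function(x, y, bandwidth, grid, weights = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(x))
  weights <- weights / sum(weights)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  gx <- grid$origin_x + (seq_len(nc) - 0.5) * grid$cell_size
  gy <- grid$origin_y - (seq_len(nr) - 0.5) * grid$cell_size
  # separable kernel: rows (y) x points, points x cols (x)
  ky <- outer(gy, y, function(g, p) stats::dnorm(g, p, bandwidth[2L]))
  kx <- outer(x, gx, function(p, g) stats::dnorm(g, p, bandwidth[1L]))
  dens <- (ky * rep(weights, each = nr)) %*% kx
  raster_grid(dens, grid$origin_x, grid$origin_y, grid$cell_size,
              grid$nodata, grid$crs_tag)
}

#' Extract core habitat as KDE isopleth polygons
#'
#' Source points are the centers of cells whose HSI value strictly exceeds
#' `cutoff` (default 4, so classes 5-7 qualify). A Gaussian KDE over the
#' source points is evaluated on the raster lattice; the isopleth is the
#' smallest-density level set whose cells hold at least `isopleth` of the
#' total KDE mass on the evaluation grid (volume-contour method: sort cell
#' densities descending and accumulate cell mass). The selected cells are
#' vectorized into polygons (holes preserved).
#'
#' @param hsi an `hsi_grid` (or any `raster_grid` of scores).
#' @param cutoff cells must exceed this value to act as KDE sources.
#' @param isopleth mass fraction the level set must contain (0 < f < 1).
#' @param bandwidth KDE bandwidth (km, length 1 or 2); default Scott's rule
#'   on the source coordinates.
#' @return a `core_habitat`: list with `polygons`, `kde_bandwidth`,
#'   `isopleth_level`, `source_cell_count`, `enclosed_mass`, `density`
#'   raster, and the logical `selected` matrix.
#' @export
extract_core_habitat <- function(hsi, cutoff = 4, isopleth = 0.90,
                                 bandwidth = NULL) {
  stopifnot(isopleth > 0, isopleth < 1)
  cc <- cell_centers(hsi)
  src <- cc[!is.na(cc$value) & cc$value > cutoff, , drop = FALSE]
  if (!nrow(src)) {
    warning("no cell exceeds the HSI cutoff; core habitat is empty")
    return(structure(list(polygons = list(), kde_bandwidth = NULL,
                          isopleth_level = isopleth, source_cell_count = 0L,
                          enclosed_mass = 0, density = NULL, selected = NULL),
                     class = "core_habitat"))
  }
  if (is.null(bandwidth)) bandwidth <- scott_bandwidth(src$x, src$y)
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, 2L)
  dens <- kde_surface(src$x, src$y, bandwidth, hsi)
  mass <- dens$values * hsi$cell_size^2
  mass <- mass / sum(mass)
  ord <- order(as.vector(mass), decreasing = TRUE)
  cum <- cumsum(as.vector(mass)[ord])
  n_in <- which(cum >= isopleth)[1L]
  sel <- matrix(FALSE, nrow(mass), ncol(mass))
  sel[ord[seq_len(n_in)]] <- TRUE
  polys <- polygonize_cells(sel, hsi)
  structure(list(polygons = polys, kde_bandwidth = bandwidth,
                 isopleth_level = isopleth, source_cell_count = nrow(src),
                 enclosed_mass = cum[n_in], density = dens, selected = sel),
            class = "core_habitat")
}

#' @export
print.core_habitat <- function(x, ...) {
  cat(sprintf("core_habitat: %d polygon(s) from %d source cells, %.1f%% isopleth (mass %.3f)\n",
              length(x$polygons), x$source_cell_count,
              100 * x$isopleth_level, x$enclosed_mass))
  invisible(x)
}

#' Vectorize a logical cell mask into boundary polygons
#'
#' Collects the boundary segments of the selected-cell squares as directed
#' edges with the region interior on the left, chains them into closed
#' rings (at pinch vertices the leftmost turn is taken), and groups
#' counter-clockwise rings (outers) with the clockwise rings (holes) they
#' contain.
#'
#' @param sel logical matrix over the grid cells.
#' @param grid `raster_grid` supplying the geotransform.
#' @return list of polygon objects (`id`, `rings`).
#' @export
polygonize_cells <- function(sel, grid) {
  if (!any(sel)) return(list())
  cs <- grid$cell_size; ox <- grid$origin_x; oy <- grid$origin_y
  nr <- nrow(sel); nc <- ncol(sel)
  sel_at <- function(r, c) r >= 1L & r <= nr & c >= 1L & c <= nc & sel[cbind(pmax(pmin(r, nr), 1L), pmax(pmin(c, nc), 1L))]
  idx <- which(sel, arr.ind = TRUE)
  # vertex (i, j): corner at x = ox + j*cs, y = oy - i*cs, i in 0..nr, j in 0..nc
  from <- character(0); to <- character(0)
  vkey <- function(i, j) paste(i, j)
  add <- function(i1, j1, i2, j2) {
    from <<- c(from, vkey(i1, j1)); to <<- c(to, vkey(i2, j2))
  }
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1L]; c <- idx[k, 2L]
    # CCW in map coordinates, interior on the left
    if (!sel_at(r + 1L, c)) add(r, c - 1L, r, c)          # bottom: left -> right
    if (!sel_at(r, c + 1L)) add(r, c, r - 1L, c)          # right: down -> up
    if (!sel_at(r - 1L, c)) add(r - 1L, c, r - 1L, c - 1L) # top: right -> left
    if (!sel_at(r, c - 1L)) add(r - 1L, c - 1L, r, c - 1L) # left: up -> down
  }
  used <- rep(FALSE, length(from))
  out_by_vertex <- split(seq_along(from), from)
  dir_of <- function(e) {
    a <- as.integer(strsplit(from[e], " ")[[1L]])
    b <- as.integer(strsplit(to[e], " ")[[1L]])
    c(b[2L] - a[2L], a[1L] - b[1L])  # (dx, dy) in map orientation
  }
  rings <- list()
  for (start in seq_along(from)) {
    if (used[start]) next
    ring <- from[start]
    e <- start
    repeat {
      used[e] <- TRUE
      ring <- c(ring, to[e])
      if (to[e] == from[start]) break
      cand <- out_by_vertex[[to[e]]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break  # should not happen on a closed boundary
      if (length(cand) == 1L) { e <- cand; next }
      d <- dir_of(e)
      # prefer the leftmost turn: left > straight > right
      turn <- vapply(cand, function(ce) {
        nd <- dir_of(ce)
        cross <- d[1L] * nd[2L] - d[2L] * nd[1L]  # >0 left, 0 straight, <0 right
        dot <- d[1L] * nd[1L] + d[2L] * nd[2L]
        if (cross > 0) 3 else if (dot > 0) 2 else if (cross < 0) 1 else 0
      }, 0)
      e <- cand[order(-turn)[1L]]
    }
    ij <- do.call(rbind, lapply(strsplit(ring, " "), as.integer))
    coords <- cbind(ox + ij[, 2L] * cs, oy - ij[, 1L] * cs)
    rings[[length(rings) + 1L]] <- coords
  }
  areas <- vapply(rings, polygon_area, 0)
  outers <- which(areas > 0)
  holes <- which(areas < 0)
  polys <- lapply(seq_along(outers), function(i) {
    ring <- rings[[outers[i]]]
    p <- list(id = i, rings = list(ring))
    for (h in holes) {
      hm <- rings[[h]]
      # the hole interior lies just right of the first directed segment
      # (region interior is kept on the left of every boundary edge)
      mid <- (hm[1L, ] + hm[2L, ]) / 2
      d <- hm[2L, ] - hm[1L, ]
      d <- d / sqrt(sum(d^2))
      interior <- mid + 0.25 * grid$cell_size * c(d[2L], -d[1L])
      if (point_in_polygon(list(rings = list(ring)), interior[1L], interior[2L]))
        p$rings[[length(p$rings) + 1L]] <- rings[[h]]
    }
    p
  })
  polys
}
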