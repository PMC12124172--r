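#' GeoJSON I/O
#'
#' Minimal deterministic GeoJSON writers/readers for the three geometry
#' kinds the pipeline exchanges: destination/origin points, habitat
#' polygons (with holes; multi-part allowed), and route LineStrings.
#' Polygons are represented in R as lists with an `id`, optional
#' `properties`, and `rings`: a list of closed n x 2 coordinate matrices,
#' the first ring the outer boundary (counter-clockwise), the rest holes.
#'
#' @name geojson
NULL

close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1L, ], m[nrow(m), ]))) m <- rbind(m, m[1L, ])
  m
}

geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write points as a GeoJSON FeatureCollection
#' @param points data.frame with columns x, y; other columns become properties.
#' @param path output file.
#' @return invisibly the path.
#' @export
write_geojson_points <- function(points, path) {
  stopifnot(all(c("x", "y") %in% names(points)))
  extra <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    props <- as.list(points[i, extra, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = I(c(points$x[i], points$y[i]))),
         properties = props)
  })
  geojson_write(feats, path)
}

#' Read a GeoJSON FeatureCollection of points
#' @param path file path.
#' @return data.frame with x, y plus property columns.
#' @export
read_geojson_points <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!length(fc$features))
    return(data.frame(x = numeric(0), y = numeric(0)))
  rows <- lapply(fc$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    props <- f$properties
    c(list(x = cc[1L], y = cc[2L]), props)
  })
  do.call(rbind.data.frame, c(rows, make.row.names = FALSE))
}

#' Write polygons as a GeoJSON FeatureCollection
#' @param polygons list of polygon objects (see [geojson]).
#' @param path output file.
#' @return invisibly the path.
#' @export
write_geojson_polygons <- function(polygons, path) {
  feats <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    coords <- lapply(p$rings, function(r) {
      r <- close_ring(as.matrix(r))
      lapply(seq_len(nrow(r)), function(j) I(unname(r[j, ])))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = c(list(id = p$id %||% i), p$properties))
  })
  geojson_write(feats, path)
}

#' Read a GeoJSON FeatureCollection of polygons
#' @param path file path.
#' @return list of polygon objects with `id`, `rings`, `properties`.
#' @export
read_geojson_polygons <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    geom <- f$geometry
    ring_sets <- if (identical(geom$type, "MultiPolygon"))
      do.call(c, geom$coordinates) else geom$coordinates
    rings <- lapply(ring_sets, function(r) {
      m <- do.call(rbind, lapply(r, function(pt) as.numeric(unlist(pt))))
      unname(m)
    })
    list(id = f$properties$id, rings = rings,
         properties = f$properties[setdiff(names(f$properties), "id")])
  })
}

#' Write routes as GeoJSON LineStrings
#'
#' Each route becomes a LineString feature with properties `origin_id`,
#' `destination_id`, `weight_type`, `total_km`, `total_hours`, `rank`.
#' An empty route list writes a valid empty FeatureCollection.
#'
#' @param routes list of route objects (see [shortest_path()]).
#' @param network the `transport_network` the routes refer to (for node
#'   coordinates).
#' @param path output file.
#' @return invisibly the path.
#' @export
write_routes <- function(routes, network, path) {
  feats <- lapply(seq_along(routes), function(i) {
    r <- routes[[i]]
    idx <- match(r$nodes, network$nodes$id)
    if (anyNA(idx)) stop("route references nodes absent from the network")
    coords <- lapply(idx, function(j)
      I(c(network$nodes$x[j], network$nodes$y[j])))
    list(type = "Feature",
         geometry = list(type = "LineString", coordinates = coords),
         properties = list(origin_id = r$nodes[1L],
                           destination_id = r$nodes[length(r$nodes)],
                           weight_type = r$weight_type,
                           total_km = r$total_km,
                           total_hours = r$total_h,
                           rank = r$rank %||% 1L))
  })
  geojson_write(feats, path)
}

#' Read routes written by [write_routes()]
#' @param path file path.
#' @return list of route objects (coordinates, totals, weight type, rank).
#' @export
read_routes <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(pt) as.numeric(unlist(pt))))
    p <- f$properties
    list(coords = coords,
         origin_id = p$origin_id, destination_id = p$destination_id,
         weight_type = p$weight_type,
         total_km = as.numeric(p$total_km),
         total_h = as.numeric(p$total_hours),
         rank = as.integer(p$rank))
  })
}

#' Test points against a polygon (even-odd rule, holes supported)
#' @param polygon a polygon object with `rings`.
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
point_in_polygon <- function(polygon, x, y) {
  inside <- rep(FALSE, length(x))
  for (ring in polygon$rings) {
    m <- as.matrix(ring)
    # drop closing vertex if present
    if (isTRUE(all.equal(m[1L, ], m[nrow(m), ]))) m <- m[-nrow(m), , drop = FALSE]
    n <- nrow(m)
    j <- n
    cross <- rep(FALSE, length(x))
    for (i in seq_len(n)) {
      xi <- m[i, 1L]; yi <- m[i, 2L]; xj <- m[j, 1L]; yj <- m[j, 2L]
      hit <- ((yi > y) != (yj > y)) &
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      cross <- xor(cross, hit)
      j <- i
    }
    inside <- xor(inside, cross)  # even-odd across rings: holes cancel
  }
  inside
}

polygon_area <- function(ring) {
  m <- as.matrix(ring)
  if (isTRUE(all.equal(m[1L, ], m[nrow(m), ]))) m <- m[-nrow(m), , drop = FALSE]
  n <- nrow(m)
  j <- c(n, seq_len(n - 1L))
  sum(m[j, 1L] * m[, 2L] - m[, 1L] * m[j, 2L]) / 2
}
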