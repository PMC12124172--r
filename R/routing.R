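#' @keywords internal
#' Run an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

edge_weight_vector <- function(network, weight = c("distance", "time")) {
  weight <- match.arg(weight)
  if (weight == "distance") network$edges$length_km else network$edges$time_h
}

# Single-source Dijkstra over node indices. Deterministic: among equal
# tentative costs the smallest node id is settled first, and relaxation
# updates only on strict improvement (ties keep the earlier predecessor).
dijkstra_full <- function(network, src_idx, weight = "distance",
                          reversed = FALSE,
                          banned_nodes = integer(0), banned_edges = integer(0)) {
  ids <- network$nodes$id
  n <- length(ids)
  w <- edge_weight_vector(network, weight)
  eu <- match(network$edges$u, ids)
  ev <- match(network$edges$v, ids)
  if (reversed) { tmp <- eu; eu <- ev; ev <- tmp }
  live_edge <- rep(TRUE, length(eu))
  if (length(banned_edges)) live_edge[banned_edges] <- FALSE
  # adjacency: outgoing edge rows per node
  out_edges <- split(seq_along(eu), factor(eu, levels = seq_len(n)))
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n); prev_edge <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  if (length(banned_nodes)) done[banned_nodes] <- TRUE
  dist[src_idx] <- 0
  id_rank <- rank(ids, ties.method = "first")
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], id_rank[cand])[1L]]
    done[u] <- TRUE
    for (k in out_edges[[u]]) {
      if (!live_edge[k]) next
      v <- ev[k]
      if (done[v]) next
      nd <- dist[u] + w[k]
      if (nd < dist[v]) { dist[v] <- nd; prev[v] <- u; prev_edge[v] <- k }
    }
  }
  list(dist = dist, prev = prev, prev_edge = prev_edge)
}

route_from_prev <- function(network, dj, src_idx, dst_idx, weight) {
  if (!is.finite(dj$dist[dst_idx])) return(NULL)
  path <- integer(0); epath <- integer(0)
  v <- dst_idx
  while (v != src_idx) {
    path <- c(v, path)
    epath <- c(dj$prev_edge[v], epath)
    v <- dj$prev[v]
  }
  path <- c(src_idx, path)
  make_route(network, path, epath, weight)
}

make_route <- function(network, path_idx, epath, weight, rank = 1L) {
  structure(list(nodes = network$nodes$id[path_idx],
                 node_idx = path_idx, edge_idx = epath,
                 total_km = sum(network$edges$length_km[epath]),
                 total_h = sum(network$edges$time_h[epath]),
                 weight_type = weight, rank = rank),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("route (%s, rank %d): %d nodes, %.3f km, %.3f h\n  %s\n",
              x$weight_type, x$rank, length(x$nodes), x$total_km, x$total_h,
              paste(x$nodes, collapse = " - ")))
  invisible(x)
}

#' Shortest path between two nodes
#'
#' Dijkstra's algorithm under the chosen edge weight (km or hours), with
#' deterministic tie-breaking by node id. Unreachable destinations return
#' `NULL` (reported, never an error); unknown node ids are errors.
#'
#' @param network a `transport_network`.
#' @param src,dst node ids.
#' @param weight "distance" (km) or "time" (hours).
#' @return a `route` (ordered node ids, `total_km`, `total_h`,
#'   `weight_type`, `rank`), or `NULL` when `dst` is unreachable.
#' @export
shortest_path <- function(network, src, dst, weight = c("distance", "time")) {
  weight <- match.arg(weight)
  si <- match(as.character(src), network$nodes$id)
  di <- match(as.character(dst), network$nodes$id)
  if (is.na(si) || is.na(di))
    stop(sprintf("unknown node id '%s'", if (is.na(si)) src else dst))
  if (si == di)
    return(make_route(network, si, integer(0), weight))
  dj <- dijkstra_full(network, si, weight)
  route_from_prev(network, dj, si, di, weight)
}

route_cost <- function(r, weight)
  if (weight == "distance") r$total_km else r$total_h

#' k shortest loopless routes (Yen's algorithm)
#'
#' Ranks 1..k in nondecreasing total weight; rank 1 equals
#' [shortest_path()]. Returns fewer than `k` routes when the graph holds
#' fewer simple paths. Candidate ties break on (weight, node sequence) so
#' results are reproducible.
#'
#' @inheritParams shortest_path
#' @param k number of routes requested (>= 1).
#' @return list of `route` objects (possibly empty when unreachable).
#' @export
k_shortest_routes <- function(network, src, dst, k = 1L,
                              weight = c("distance", "time")) {
  weight <- match.arg(weight)
  stopifnot(k >= 1L)
  first <- shortest_path(network, src, dst, weight)
  if (is.null(first)) return(list())
  A <- list(first)
  B <- list()
  ids <- network$nodes$id
  eu <- match(network$edges$u, ids); ev <- match(network$edges$v, ids)
  while (length(A) < k) {
    last <- A[[length(A)]]
    lp <- last$node_idx
    for (i in seq_len(length(lp) - 1L)) {
      spur <- lp[i]
      root <- lp[seq_len(i)]
      root_edges <- last$edge_idx[seq_len(i - 1L)]
      banned_edges <- integer(0)
      for (p in A) {
        if (length(p$node_idx) > i && identical(p$node_idx[seq_len(i)], root))
          banned_edges <- c(banned_edges,
                            which(eu == p$node_idx[i] & ev == p$node_idx[i + 1L]))
      }
      banned_nodes <- setdiff(root, spur)
      dj <- dijkstra_full(network, spur, weight,
                          banned_nodes = banned_nodes,
                          banned_edges = unique(banned_edges))
      di <- match(as.character(dst), ids)
      sp <- route_from_prev(network, dj, spur, di, weight)
      if (is.null(sp)) next
      cand_nodes <- c(root[-i], sp$node_idx)
      cand_edges <- c(root_edges, sp$edge_idx)
      if (anyDuplicated(network$nodes$id[cand_nodes])) next
      key <- paste(cand_nodes, collapse = ">")
      known <- c(vapply(A, function(r) paste(r$node_idx, collapse = ">"), ""),
                 vapply(B, function(r) paste(r$node_idx, collapse = ">"), ""))
      if (key %in% known) next
      B[[length(B) + 1L]] <- make_route(network, cand_nodes, cand_edges, weight)
    }
    if (!length(B)) break
    costs <- vapply(B, route_cost, 0, weight = weight)
    keys <- vapply(B, function(r) paste(r$node_idx, collapse = ">"), "")
    best <- order(costs, keys)[1L]
    nxt <- B[[best]]
    nxt$rank <- length(A) + 1L
    A[[length(A) + 1L]] <- nxt
    B[[best]] <- NULL
  }
  for (i in seq_along(A)) A[[i]]$rank <- i
  A
}

#' Travel-time isochrone classes toward an anchor node
#'
#' Single-source Dijkstra on the edge-reversed graph gives, for every node,
#' the shortest travel time TO the anchor. Each node is binned into a
#' travel-day class `floor(time / bin_hours)` (default 8-h travel days).
#'
#' @param network a `transport_network`.
#' @param anchor node id of the destination anchoring the isochrone.
#' @param weight edge weight, normally "time".
#' @param bin_hours width of one travel-day class.
#' @return data.frame: node, x, y, time_h (Inf when unreachable),
#'   class (NA when unreachable), reachable.
#' @export
isochrone <- function(network, anchor, weight = "time", bin_hours = 8) {
  ai <- match(as.character(anchor), network$nodes$id)
  if (is.na(ai)) stop(sprintf("unknown anchor node '%s'", anchor))
  dj <- dijkstra_full(network, ai, weight, reversed = TRUE)
  t <- dj$dist
  data.frame(node = network$nodes$id,
             x = network$nodes$x, y = network$nodes$y,
             time_h = t,
             class = ifelse(is.finite(t), floor(t / bin_hours), NA),
             reachable = is.finite(t))
}

#' Sample candidate origin points inside habitat polygons
#'
#' Uniform rejection sampling within each polygon (even-odd rule, so holes
#' are excluded). Zero-area polygons are skipped with a warning.
#'
#' @param polygons list of polygon objects.
#' @param n_per_polygon points per polygon (default 100).
#' @param seed RNG seed; global RNG state is restored afterwards.
#' @return data.frame: polygon_id, x, y.
#' @export
sample_origins <- function(polygons, n_per_polygon = 100, seed = 1) {
  if (!length(polygons))
    return(data.frame(polygon_id = character(0), x = numeric(0), y = numeric(0)))
  with_seed(seed, {
    out <- list()
    for (i in seq_along(polygons)) {
      p <- polygons[[i]]
      area <- sum(vapply(p$rings, polygon_area, 0))  # holes are CW => negative
      if (abs(area) <= 0) {
        warning(sprintf("polygon %s has zero area; skipped", p$id %||% i))
        next
      }
      allm <- do.call(rbind, lapply(p$rings, as.matrix))
      bx <- range(allm[, 1L]); by <- range(allm[, 2L])
      got <- matrix(numeric(0), ncol = 2L)
      tries <- 0L
      while (nrow(got) < n_per_polygon && tries < 1000L) {
        m <- max(4L * n_per_polygon, 64L)
        cx <- stats::runif(m, bx[1L], bx[2L])
        cy <- stats::runif(m, by[1L], by[2L])
        ok <- point_in_polygon(p, cx, cy)
        got <- rbind(got, cbind(cx[ok], cy[ok]))
        tries <- tries + 1L
      }
      got <- got[seq_len(min(n_per_polygon, nrow(got))), , drop = FALSE]
      out[[length(out) + 1L]] <-
        data.frame(polygon_id = as.character(p$id %||% i),
                   x = got[, 1L], y = got[, 2L])
    }
    if (!length(out))
      return(data.frame(polygon_id = character(0), x = numeric(0), y = numeric(0)))
    do.call(rbind, out)
  })
}

#' Snap points to their nearest network nodes
#'
#' Each point maps to the nearest node (planar distance; ties to the
#' smaller node id). Points sharing a nearest node are collapsed: the
#' unique node set is what routing uses, with collapse counts retained.
#'
#' @param points data.frame with x, y (and optionally polygon_id).
#' @param network a `transport_network` (non-empty).
#' @return an `origin_set`: list with `points` (input plus `node` column),
#'   `unique_nodes`, `counts` (points per unique node), `n_points`,
#'   `n_unique`.
#' @export
snap_to_network <- function(points, network) {
  if (!nrow(network$nodes)) stop("cannot snap to an empty network")
  nx <- network$nodes$x; ny <- network$nodes$y; ids <- network$nodes$id
  ord <- order(ids)
  snap <- character(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (nx - points$x[i])^2 + (ny - points$y[i])^2
    snap[i] <- ids[order(d2, rank(ids, ties.method = "first"))[1L]]
  }
  points$node <- snap
  counts <- table(snap)
  uniq <- sort(unique(snap))
  structure(list(points = points, unique_nodes = uniq,
                 counts = counts[uniq],
                 n_points = nrow(points), n_unique = length(uniq)),
            class = "origin_set")
}

#' @export
print.origin_set <- function(x, ...) {
  cat(sprintf("origin_set: %d sampled points -> %d unique network nodes\n",
              x$n_points, x$n_unique))
  invisible(x)
}

#' Per-node transit counts over a set of routes (bottleneck analysis)
#'
#' Counts how many routes pass through each node; optionally a Gaussian
#' kernel density surface over node coordinates weighted by counts, and a
#' ranked bottleneck table.
#'
#' @param routes list of `route` objects.
#' @param network a `transport_network` (supplies coordinates and the full
#'   node universe; nodes on no route count 0).
#' @param density_bandwidth_km optional KDE bandwidth; `NULL` skips the
#'   surface.
#' @param density_grid optional `raster_grid` template for the surface.
#' @param top_m rows in the bottleneck table.
#' @return a `node_load`: list with `counts` (node, x, y, count),
#'   `bottlenecks` (top `top_m` by count), and optional `density` raster.
#' @export
node_transit_counts <- function(routes, network, density_bandwidth_km = NULL,
                                density_grid = NULL, top_m = 10L) {
  all_nodes <- unlist(lapply(routes, function(r) r$nodes))
  tab <- table(factor(all_nodes, levels = network$nodes$id))
  counts <- data.frame(node = network$nodes$id,
                       x = network$nodes$x, y = network$nodes$y,
                       count = as.integer(tab))
  ord <- order(-counts$count, counts$node)
  bottlenecks <- counts[ord, ][seq_len(min(top_m, nrow(counts))), , drop = FALSE]
  dens <- NULL
  if (!is.null(density_bandwidth_km) && !is.null(density_grid) &&
      sum(counts$count) > 0) {
    w <- counts$count[counts$count > 0]
    dens <- kde_surface(counts$x[counts$count > 0], counts$y[counts$count > 0],
                        bandwidth = rep(density_bandwidth_km, 2L),
                        grid = density_grid, weights = w)
  }
  structure(list(counts = counts, bottlenecks = bottlenecks, density = dens),
            class = "node_load")
}

#' @export
print.node_load <- function(x, ...) {
  cat(sprintf("node_load: %d nodes, total transits %d\n",
              nrow(x$counts), sum(x$counts$count)))
  print(utils::head(x$bottlenecks, 5L))
  invisible(x)
}

#' Route a full origin-polygon to destination scenario
#'
#' Samples ~`n_per_polygon` origin points per habitat polygon, snaps them
#' (and the destinations) to nearest network nodes, deduplicates, and
#' computes origin-by-destination optimal routes under both edge weights
#' (distance and time). Unreachable pairs are counted, never dropped
#' silently.
#'
#' @param network a `transport_network`.
#' @param polygons habitat polygons (origins are sampled inside them).
#' @param destinations data.frame of destination points with x, y
#'   (optionally id).
#' @param n_per_polygon origin points sampled per polygon.
#' @param k routes per origin-destination pair (k > 1 uses Yen's
#'   k-shortest).
#' @param seed RNG seed for origin sampling.
#' @return a `scenario_result`: routes (per weight type), `node_load`
#'   (bottlenecks over rank-1 time routes), `origin_set`,
#'   `destination_nodes`, and a `summary` (reachable fraction,
#'   per-destination mean hours, infeasible flag).
#' @export
run_scenario <- function(network, polygons, destinations,
                         n_per_polygon = 100, k = 1L, seed = 1) {
  pts <- sample_origins(polygons, n_per_polygon, seed)
  origin_set <- snap_to_network(pts, network)
  dsnap <- snap_to_network(destinations, network)
  dest_nodes <- dsnap$unique_nodes
  origins <- origin_set$unique_nodes
  ids <- network$nodes$id
  routes <- list(distance = list(), time = list())
  n_pairs <- 0L; n_reached <- 0L
  for (weight in c("distance", "time")) {
    for (o in origins) {
      if (k == 1L) {
        dj <- dijkstra_full(network, match(o, ids), weight)
        for (d in dest_nodes) {
          if (weight == "time") n_pairs <- n_pairs + 1L
          r <- route_from_prev(network, dj, match(o, ids), match(d, ids), weight)
          if (is.null(r) && o == d)
            r <- make_route(network, match(o, ids), integer(0), weight)
          if (!is.null(r)) {
            if (weight == "time") n_reached <- n_reached + 1L
            routes[[weight]][[length(routes[[weight]]) + 1L]] <- r
          }
        }
      } else {
        for (d in dest_nodes) {
          if (weight == "time") n_pairs <- n_pairs + 1L
          rs <- k_shortest_routes(network, o, d, k, weight)
          if (length(rs) && weight == "time") n_reached <- n_reached + 1L
          routes[[weight]] <- c(routes[[weight]], rs)
        }
      }
    }
  }
  time_r1 <- Filter(function(r) r$rank == 1L, routes$time)
  load <- node_transit_counts(time_r1, network)
  per_dest <- vapply(dest_nodes, function(d) {
    tt <- vapply(Filter(function(r) r$nodes[length(r$nodes)] == d, time_r1),
                 function(r) r$total_h, 0)
    if (length(tt)) mean(tt) else NA_real_
  }, 0)
  summary <- list(n_origin_points = origin_set$n_points,
                  n_origins = length(origins),
                  n_destinations = length(dest_nodes),
                  n_pairs = n_pairs,
                  reachable_fraction = if (n_pairs) n_reached / n_pairs else NA_real_,
                  mean_hours_by_destination = per_dest,
                  infeasible = n_reached == 0L)
  structure(list(routes = routes, node_load = load, origin_set = origin_set,
                 destination_nodes = dest_nodes, summary = summary),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("scenario: %d origins x %d destinations, reachable %.1f%%%s\n",
              s$n_origins, s$n_destinations, 100 * s$reachable_fraction,
              if (s$infeasible) " [INFEASIBLE]" else ""))
  invisible(x)
}
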