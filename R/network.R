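#' Default speeds (km/h) by road class
#'
#' Used when an input network omits a speed. Water edges default to the
#' dhow speed, 20 knots = 37.04 km/h.
#' @return named numeric vector of km/h.
#' @export
class_default_speeds <- function() {
  c(motorway = 100, trunk = 80, primary = 70, secondary = 60,
    tertiary = 40, residential = 30, water = 20 * 1.852)
}

#' Knots to km/h
#' @param knots speed in knots (1 knot = 1.852 km/h).
#' @return speed in km/h.
#' @export
knots_to_kmh <- function(knots) knots * 1.852

#' Construct a multimodal transport network
#'
#' Directed weighted graph over georeferenced nodes. Input edges carry a
#' `oneway` flag; two-way edges are expanded to reciprocal directed edges
#' with equal attributes. Travel time per edge is `length_km / speed_kmh`.
#'
#' @param nodes data.frame with columns `id` (unique), `x`, `y`; extra
#'   columns (e.g. landmass labels) are kept.
#' @param edges data.frame with columns `u`, `v`, `length_km`, `mode`,
#'   `oneway` (logical) and optionally `speed_kmh` (filled from
#'   [class_default_speeds()] with a warning when missing).
#' @return object of class `transport_network` with fully directed edges.
#' @export
transport_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges)) {
    stopifnot(all(c("u", "v", "length_km", "mode") %in% names(edges)))
    edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
    unknown <- setdiff(c(edges$u, edges$v), nodes$id)
    if (length(unknown))
      stop(sprintf("edge references unknown node(s): %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")))
    if (any(edges$length_km <= 0))
      stop("edge lengths must be positive")
    if (is.null(edges$oneway)) edges$oneway <- FALSE
    edges$oneway <- as.logical(edges$oneway)
    if (is.null(edges$speed_kmh)) edges$speed_kmh <- NA_real_
    miss <- is.na(edges$speed_kmh)
    if (any(miss)) {
      defs <- class_default_speeds()
      edges$speed_kmh[miss] <- defs[edges$mode[miss]]
      if (anyNA(edges$speed_kmh))
        stop("missing speed for unrecognized mode(s): ",
             paste(unique(edges$mode[is.na(edges$speed_kmh)]), collapse = ", "))
      warning(sprintf("filled %d missing edge speed(s) from class defaults",
                      sum(miss)))
    }
    if (any(edges$speed_kmh <= 0)) stop("edge speeds must be positive")
    # expand two-way edges to reciprocal directed edges
    twoway <- edges[!edges$oneway, , drop = FALSE]
    if (nrow(twoway)) {
      rev <- twoway
      rev$u <- twoway$v; rev$v <- twoway$u
      edges <- rbind(edges, rev)
    }
    edges$time_h <- edges$length_km / edges$speed_kmh
    edges <- edges[order(edges$u, edges$v, edges$mode), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = character(0), v = character(0),
                        length_km = numeric(0), speed_kmh = numeric(0),
                        mode = character(0), oneway = logical(0),
                        time_h = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "transport_network")
}

#' @export
print.transport_network <- function(x, ...) {
  cat(sprintf("transport_network: %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    tb <- table(x$edges$mode)
    cat("  modes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

# directed edges in one direction only (undirected representation for I/O):
# a (u,v) edge with oneway FALSE has a reciprocal row; keep u < v copy once.
undirected_edge_view <- function(network) {
  e <- network$edges
  if (!nrow(e)) return(e)
  keep <- e$oneway | (e$u < e$v) |
    (e$u == e$v)  # self loops (shouldn't occur) kept once
  e[keep, , drop = FALSE]
}

#' Add sea crossings to a network
#'
#' Adds bidirectional water-mode edges at dhow speed (default 20 knots =
#' 37.04 km/h); all other edges are untouched.
#'
#' @param network a `transport_network`.
#' @param crossings data.frame with columns `u`, `v`, `length_km`.
#' @param speed_knots vessel speed in knots.
#' @return the augmented network.
#' @export
add_water_routes <- function(network, crossings, speed_knots = 20) {
  if (is.null(crossings) || nrow(crossings) == 0L) return(network)
  crossings <- as.data.frame(crossings)
  unknown <- setdiff(c(as.character(crossings$u), as.character(crossings$v)),
                     network$nodes$id)
  if (length(unknown))
    stop(sprintf("water crossing references unknown node(s): %s",
                 paste(unknown, collapse = ", ")))
  if (any(crossings$length_km <= 0)) stop("crossing lengths must be positive")
  new_edges <- data.frame(u = as.character(crossings$u),
                          v = as.character(crossings$v),
                          length_km = crossings$length_km,
                          speed_kmh = knots_to_kmh(speed_knots),
                          mode = "water", oneway = FALSE)
  old <- undirected_edge_view(network)
  old <- old[, c("u", "v", "length_km", "speed_kmh", "mode", "oneway")]
  transport_network(network$nodes, rbind(old, new_edges))
}

#' Simplify a network while preserving routing
#'
#' Removes interstitial nodes (degree-2 pass-through nodes along a chain of
#' uniform mode, not listed in `protect`) and merges their incident edges:
#' merged length is the sum of lengths, merged time the sum of times, and
#' merged speed `length/time` (the harmonic combination). Two-way chains and
#' direction-consistent one-way chains are both merged. With
#' `consolidate_radius_km > 0`, node clusters within that radius collapse to
#' their centroid (single-linkage), edges are re-targeted and self-loops
#' dropped; consolidation intentionally changes geometry and is off by
#' default.
#'
#' @param network a `transport_network`.
#' @param consolidate_radius_km cluster radius, 0 disables consolidation.
#' @param protect node ids never removed (origin/destination anchors).
#' @return list with `network` (simplified) and `mapping`
#'   (data.frame old_id, new_id).
#' @export
simplify_network <- function(network, consolidate_radius_km = 0,
                             protect = character(0)) {
  nodes <- network$nodes
  e <- undirected_edge_view(network)
  e <- e[, c("u", "v", "length_km", "speed_kmh", "mode", "oneway")]
  e$time_h <- e$length_km / e$speed_kmh
  mapping <- data.frame(old_id = nodes$id, new_id = nodes$id,
                        stringsAsFactors = FALSE)

  repeat {
    removed_any <- FALSE
    for (n in setdiff(nodes$id, protect)) {
      inc <- which(e$u == n | e$v == n)
      if (length(inc) == 0L) next
      nb <- unique(c(e$u[inc], e$v[inc]))
      nb <- setdiff(nb, n)
      if (length(nb) != 2L) next
      if (length(unique(e$mode[inc])) != 1L) next
      a <- nb[1L]; b <- nb[2L]
      sub <- e[inc, , drop = FALSE]
      two_an <- which(!sub$oneway & ((sub$u == a & sub$v == n) | (sub$u == n & sub$v == a)))
      two_nb <- which(!sub$oneway & ((sub$u == n & sub$v == b) | (sub$u == b & sub$v == n)))
      one_in  <- which(sub$oneway & sub$v == n)
      one_out <- which(sub$oneway & sub$u == n)
      merged <- NULL
      if (length(inc) == 2L && length(two_an) == 1L && length(two_nb) == 1L) {
        # two-way chain a - n - b
        merged <- data.frame(u = a, v = b,
                             length_km = sum(sub$length_km),
                             time_h = sum(sub$time_h),
                             mode = sub$mode[1L], oneway = FALSE)
      } else if (length(inc) == 2L && length(one_in) == 1L &&
                 length(one_out) == 1L &&
                 sub$u[one_in] != sub$v[one_out]) {
        # direction-consistent one-way chain u -> n -> v
        merged <- data.frame(u = sub$u[one_in], v = sub$v[one_out],
                             length_km = sum(sub$length_km),
                             time_h = sum(sub$time_h),
                             mode = sub$mode[1L], oneway = TRUE)
      }
      if (is.null(merged)) next
      # skip if a parallel edge already links the endpoints (keep both paths)
      par <- (e$u == merged$u & e$v == merged$v) |
        (!merged$oneway & e$u == merged$v & e$v == merged$u)
      if (any(par & !(seq_len(nrow(e)) %in% inc))) next
      merged$speed_kmh <- merged$length_km / merged$time_h
      e <- rbind(e[-inc, , drop = FALSE],
                 merged[, c("u", "v", "length_km", "speed_kmh", "mode",
                            "oneway", "time_h")])
      nodes <- nodes[nodes$id != n, , drop = FALSE]
      mapping$new_id[mapping$new_id == n] <- NA_character_
      removed_any <- TRUE
    }
    if (!removed_any) break
  }
  # removed interstitial nodes map to the nearer retained chain endpoint:
  # record simply as dropped (NA) -> resolved below via nearest retained node
  dropped <- is.na(mapping$new_id)
  if (any(dropped)) {
    old_nodes <- network$nodes
    for (i in which(dropped)) {
      oi <- match(mapping$old_id[i], old_nodes$id)
      d2 <- (nodes$x - old_nodes$x[oi])^2 + (nodes$y - old_nodes$y[oi])^2
      mapping$new_id[i] <- nodes$id[order(d2, nodes$id)[1L]]
    }
  }

  if (consolidate_radius_km > 0 && nrow(nodes) > 1L) {
    cl <- single_linkage_clusters(nodes$x, nodes$y, consolidate_radius_km)
    keep_id <- vapply(split(seq_len(nrow(nodes)), cl),
                      function(ix) nodes$id[ix][order(nodes$id[ix])[1L]], "")
    cx <- vapply(split(nodes$x, cl), mean, 0)
    cy <- vapply(split(nodes$y, cl), mean, 0)
    new_nodes <- data.frame(id = keep_id, x = cx, y = cy,
                            stringsAsFactors = FALSE)
    remap <- stats::setNames(keep_id[as.character(cl)], nodes$id)
    e$u <- unname(remap[e$u]); e$v <- unname(remap[e$v])
    e <- e[e$u != e$v, , drop = FALSE]
    dup <- duplicated(e[, c("u", "v", "mode", "oneway")])
    e <- e[!dup, , drop = FALSE]
    mapping$new_id <- unname(remap[mapping$new_id])
    nodes <- new_nodes
  }

  out <- transport_network(nodes,
                           e[, c("u", "v", "length_km", "speed_kmh", "mode", "oneway")])
  list(network = out, mapping = mapping)
}

single_linkage_clusters <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    d <- sqrt((x[(i + 1L):n] - x[i])^2 + (y[(i + 1L):n] - y[i])^2)
    for (j in which(d <= radius)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Summary statistics of a transport network
#'
#' @param network a `transport_network`.
#' @return list: `n_nodes`, `n_edges` (directed), `length_by_mode` (km,
#'   directed totals), `n_components` (weak).
#' @export
network_stats <- function(network) {
  e <- network$edges
  comp <- if (nrow(network$nodes)) weak_components(network) else integer(0)
  list(n_nodes = nrow(network$nodes),
       n_edges = nrow(e),
       length_by_mode = if (nrow(e))
         tapply(e$length_km, e$mode, sum) else numeric(0),
       n_components = if (length(comp)) max(comp) else 0L)
}

weak_components <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ui <- match(network$edges$u, ids); vi <- match(network$edges$v, ids)
  for (k in seq_along(ui)) {
    ri <- find(ui[k]); rj <- find(vi[k])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}
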