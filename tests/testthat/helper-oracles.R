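# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive enumeration, O(n^2) pair counting, winding numbers)
# so they share no code path with the package implementations they check.

# --- brute-force simple-path enumeration ---------------------------------
# Returns all simple src->dst paths as list(nodes = ids, cost = total).
enumerate_simple_paths <- function(network, src, dst, weight = "distance") {
  ids <- network$nodes$id
  e <- network$edges
  w <- if (weight == "distance") e$length_km else e$time_h
  out <- list()
  recurse <- function(path, cost) {
    cur <- path[length(path)]
    if (cur == dst) {
      out[[length(out) + 1L]] <<- list(nodes = path, cost = cost)
      return(invisible())
    }
    nxt <- which(e$u == cur)
    for (k in nxt) {
      if (e$v[k] %in% path) next
      recurse(c(path, e$v[k]), cost + w[k])
    }
  }
  recurse(src, 0)
  out
}

best_path_oracle <- function(network, src, dst, weight = "distance") {
  paths <- enumerate_simple_paths(network, src, dst, weight)
  if (!length(paths)) return(NULL)
  costs <- vapply(paths, function(p) p$cost, 0)
  keys <- vapply(paths, function(p) paste(p$nodes, collapse = ">"), "")
  paths[[order(costs, keys)[1L]]]
}

sorted_path_costs_oracle <- function(network, src, dst, weight = "distance") {
  paths <- enumerate_simple_paths(network, src, dst, weight)
  sort(vapply(paths, function(p) p$cost, 0))
}

# --- random directed graph fixtures --------------------------------------
random_network <- function(n_nodes = 6, p_edge = 0.4, oneway_frac = 0.5,
                           seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- data.frame(id = ids,
                      x = runif(n_nodes, 0, 50), y = runif(n_nodes, 0, 50))
  pairs <- expand.grid(u = ids, v = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$u < pairs$v, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  if (!nrow(pairs)) pairs <- data.frame(u = ids[1L], v = ids[2L])
  pairs$length_km <- round(runif(nrow(pairs), 1, 20), 3)
  pairs$speed_kmh <- sample(c(30, 60, 100), nrow(pairs), replace = TRUE)
  pairs$mode <- "primary"
  pairs$oneway <- runif(nrow(pairs)) < oneway_frac
  transport_network(nodes, pairs)
}

# network with degree-2 chains for simplification tests
chained_network <- function(seed = 1, n_chains = 2, chain_nodes = 3) {
  cfg <- synth_config(grid_rows = 16, grid_cols = 16,
                      network_spec = list(nodes_per_side = 3,
                                          n_chains = n_chains,
                                          chain_nodes = chain_nodes),
                      seed = seed)
  gen_transport_network(cfg)
}

# --- AUC / maxSSS oracles -------------------------------------------------
auc_pair_oracle <- function(sp, sb) {
  tot <- 0
  for (p in sp) for (b in sb)
    tot <- tot + if (p > b) 1 else if (p == b) 0.5 else 0
  tot / (length(sp) * length(sb))
}

auc_ranksum_oracle <- function(sp, sb) {
  r <- rank(c(sp, sb), ties.method = "average")
  np <- length(sp)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(sb))
}

maxsss_exhaustive_oracle <- function(sp, sb) {
  cand <- sort(unique(c(sp, sb)))
  best_t <- NA_real_; best <- -Inf
  for (t in cand) {
    sens <- mean(sp >= t); spec <- mean(sb < t)
    v <- (sens + spec) / 2
    if (v > best + 1e-15) { best <- v; best_t <- t }
  }
  best_t
}

# --- winding-number point-in-polygon oracle ------------------------------
pip_winding_oracle <- function(ring, px, py) {
  m <- as.matrix(ring)
  if (isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- m[-nrow(m), , drop = FALSE]
  n <- nrow(m)
  wn <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (m[i, 2] <= py) {
      if (m[j, 2] > py &&
          (m[j, 1] - m[i, 1]) * (py - m[i, 2]) -
          (px - m[i, 1]) * (m[j, 2] - m[i, 2]) > 0) wn <- wn + 1L
    } else {
      if (m[j, 2] <= py &&
          (m[j, 1] - m[i, 1]) * (py - m[i, 2]) -
          (px - m[i, 1]) * (m[j, 2] - m[i, 2]) < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

# --- small co-registered raster builders ---------------------------------
tiny_grid <- function(values, cell_size = 1) {
  raster_grid(matrix(values[[1]], values[[2]], values[[3]]),
              cell_size = cell_size)
}

grid_from_matrix <- function(m) raster_grid(m)
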