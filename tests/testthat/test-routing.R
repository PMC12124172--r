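triangle_network <- function() {
  nodes <- data.frame(id = c("A", "B", "C"), x = c(0, 1, 2), y = 0)
  edges <- data.frame(u = c("A", "B", "A"), v = c("B", "C", "C"),
                      length_km = c(1, 1, 3), speed_kmh = 60,
                      mode = "primary", oneway = FALSE)
  transport_network(nodes, edges)
}

test_that("shortest path handles identity, detours and directedness", {
  net <- triangle_network()
  same <- shortest_path(net, "A", "A")
  expect_identical(same$nodes, "A")
  expect_equal(same$total_km, 0)
  r <- shortest_path(net, "A", "C", "distance")
  expect_identical(r$nodes, c("A", "B", "C"))
  expect_equal(r$total_km, 2)
  # one-way edge A->B only: B cannot reach A
  ow <- transport_network(data.frame(id = c("A", "B"), x = 0:1, y = 0),
                          data.frame(u = "A", v = "B", length_km = 1,
                                     speed_kmh = 50, mode = "primary",
                                     oneway = TRUE))
  expect_null(shortest_path(ow, "B", "A"))
  expect_error(shortest_path(net, "A", "nope"), "unknown node")
})

test_that("route totals equal summed edge attributes and paths are simple", {
  for (seed in 1:10) {
    net <- random_network(7, p_edge = 0.5, oneway_frac = 0.3, seed = seed)
    ids <- net$nodes$id
    r <- shortest_path(net, ids[1], ids[7], "time")
    if (is.null(r)) next
    expect_false(anyDuplicated(r$nodes) > 0)
    expect_equal(r$total_km, sum(net$edges$length_km[r$edge_idx]),
                 tolerance = 1e-9)
    expect_equal(r$total_h, sum(net$edges$time_h[r$edge_idx]),
                 tolerance = 1e-9)
  }
})

test_that("Dijkstra agrees with igraph on random fixtures", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    net <- random_network(8, p_edge = 0.45, oneway_frac = 0.4, seed = 100 + seed)
    g <- igraph::graph_from_data_frame(net$edges[, c("u", "v")],
                                       vertices = net$nodes$id)
    d_ig <- igraph::distances(g, v = net$nodes$id[1], mode = "out",
                              weights = net$edges$length_km)
    for (j in c(3, 5, 8)) {
      r <- shortest_path(net, net$nodes$id[1], net$nodes$id[j])
      mine <- if (is.null(r)) Inf else r$total_km
      expect_equal(mine, unname(d_ig[1, net$nodes$id[j]]), tolerance = 1e-9)
    }
  }
})

test_that("k-shortest routes enumerate loopless paths in order", {
  # diamond: exactly 3 simple A->D paths
  nodes <- data.frame(id = c("A", "B", "C", "D"), x = c(0, 1, 1, 2),
                      y = c(0, 1, -1, 0))
  edges <- data.frame(u = c("A", "B", "A", "C", "A"),
                      v = c("B", "D", "C", "D", "D"),
                      length_km = c(1, 1, 2, 2, 10), speed_kmh = 60,
                      mode = "primary", oneway = TRUE)
  net <- transport_network(nodes, edges)
  oracle <- sorted_path_costs_oracle(net, "A", "D", "distance")
  expect_length(oracle, 3L)
  one <- k_shortest_routes(net, "A", "D", k = 1)
  expect_equal(one[[1L]]$nodes, shortest_path(net, "A", "D")$nodes)
  all3 <- k_shortest_routes(net, "A", "D", k = 3)
  expect_equal(vapply(all3, function(r) r$total_km, 0), oracle)
  more <- k_shortest_routes(net, "A", "D", k = 10)
  expect_length(more, 3L)  # exhausted, not padded
  expect_equal(vapply(more, function(r) r$rank, 0L), 1:3)
})

test_that("k-shortest lists are sorted, distinct and prefix the enumeration", {
  for (seed in 1:10) {
    net <- random_network(6, p_edge = 0.6, oneway_frac = 0.3, seed = 50 + seed)
    src <- net$nodes$id[1]; dst <- net$nodes$id[6]
    oracle <- sorted_path_costs_oracle(net, src, dst, "time")
    ks <- k_shortest_routes(net, src, dst, k = 4, weight = "time")
    expect_length(ks, min(4L, length(oracle)))
    costs <- vapply(ks, function(r) r$total_h, 0)
    expect_false(is.unsorted(costs))
    keys <- vapply(ks, function(r) paste(r$nodes, collapse = ">"), "")
    expect_false(anyDuplicated(keys) > 0)
    if (length(oracle)) expect_equal(costs, oracle[seq_along(costs)],
                                     tolerance = 1e-9)
  }
})

test_that("triangle inequality holds over computed shortest costs", {
  net <- random_network(8, p_edge = 0.5, oneway_frac = 0.2, seed = 77)
  ids <- net$nodes$id
  cost <- function(a, b) {
    r <- shortest_path(net, a, b, "time")
    if (is.null(r)) Inf else r$total_h
  }
  set.seed(1)
  for (i in 1:15) {
    tri <- sample(ids, 3)
    expect_lte(cost(tri[1], tri[3]),
               cost(tri[1], tri[2]) + cost(tri[2], tri[3]) + 1e-9)
  }
})

test_that("isochrone times equal forward shortest paths and bin by 8 h", {
  net <- chained_network(seed = 6)
  anchor <- net$nodes$id[10]
  iso <- isochrone(net, anchor)
  expect_equal(iso$time_h[iso$node == anchor], 0)
  expect_equal(iso$class[iso$node == anchor], 0)
  set.seed(2)
  for (nid in sample(net$nodes$id, 10)) {
    r <- shortest_path(net, nid, anchor, "time")
    expected <- if (is.null(r)) Inf else r$total_h
    expect_equal(iso$time_h[iso$node == nid], expected, tolerance = 1e-9)
  }
  fin <- is.finite(iso$time_h)
  expect_equal(iso$class[fin], floor(iso$time_h[fin] / 8))
  expect_error(isochrone(net, "missing"), "unknown anchor")
})

test_that("origin sampling stays inside polygons and is seed-stable", {
  sq <- list(id = "p", rings = list(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))))
  pts <- sample_origins(list(sq), n_per_polygon = 100, seed = 5)
  expect_equal(nrow(pts), 100L)
  expect_true(all(point_in_polygon(sq, pts$x, pts$y)))
  oracle_in <- vapply(seq_len(nrow(pts)), function(i)
    pip_winding_oracle(sq$rings[[1]], pts$x[i], pts$y[i]), TRUE)
  expect_true(all(oracle_in))
  expect_identical(pts, sample_origins(list(sq), 100, seed = 5))
  expect_equal(nrow(sample_origins(list(), 100, seed = 1)), 0L)
  degenerate <- list(id = "z", rings = list(rbind(c(0, 0), c(1, 0), c(0, 0))))
  expect_warning(out <- sample_origins(list(degenerate), 10, seed = 1),
                 "zero area")
  expect_equal(nrow(out), 0L)
})

test_that("snapping matches brute force and collapses duplicates", {
  net <- random_network(20, p_edge = 0.2, seed = 8)
  set.seed(3)
  pts <- data.frame(x = runif(30, 0, 50), y = runif(30, 0, 50))
  os <- snap_to_network(pts, net)
  for (i in seq_len(nrow(pts))) {
    d2 <- (net$nodes$x - pts$x[i])^2 + (net$nodes$y - pts$y[i])^2
    expect_identical(os$points$node[i], net$nodes$id[which.min(d2)])
  }
  expect_lte(os$n_unique, os$n_points)
  # a point sitting exactly on a node snaps to it
  exact <- snap_to_network(data.frame(x = net$nodes$x[4], y = net$nodes$y[4]),
                           net)
  expect_identical(exact$points$node, net$nodes$id[4])
  # two points nearest the same node: unique count drops by one
  two <- data.frame(x = net$nodes$x[4] + c(0.01, -0.01),
                    y = net$nodes$y[4] + c(0.01, -0.01))
  os2 <- snap_to_network(two, net)
  expect_equal(os2$n_unique, os2$n_points - 1L)
})

test_that("transit counts conserve route node totals", {
  net <- triangle_network()
  r1 <- shortest_path(net, "A", "C")
  r2 <- shortest_path(net, "B", "C")
  load <- node_transit_counts(list(r1, r2), net)
  expect_equal(sum(load$counts$count), length(r1$nodes) + length(r2$nodes))
  expect_equal(load$counts$count[load$counts$node == "B"], 2L)
  empty <- node_transit_counts(list(), net)
  expect_true(all(empty$counts$count == 0L))
})

test_that("scenarios respect landmass cuts and crossing traversal", {
  cfg <- synth_config(grid_rows = 16, grid_cols = 16,
                      network_spec = list(nodes_per_side = 3,
                                          n_water_crossings = 0,
                                          n_chains = 0, oneway_frac = 0),
                      n_destinations = 5, n_polygons = 1, seed = 2)
  st <- gen_environment(cfg)
  expect_warning(net0 <- gen_transport_network(cfg), "disconnected")
  scen <- gen_scenario(st, net0, cfg)
  res0 <- run_scenario(net0, scen$polygons, scen$destinations,
                       n_per_polygon = 20, seed = 2)
  expect_equal(res0$summary$reachable_fraction, 0)
  expect_true(res0$summary$infeasible)

  # add exactly one crossing: every cross-sea route passes its endpoints
  west <- net0$nodes$id[net0$nodes$landmass == "west"]
  east <- net0$nodes$id[net0$nodes$landmass == "east"]
  wc <- west[which.max(net0$nodes$x[match(west, net0$nodes$id)])]
  ec <- east[which.min(net0$nodes$x[match(east, net0$nodes$id)])]
  len <- sqrt(sum((net0$nodes[match(wc, net0$nodes$id), c("x", "y")] -
                     net0$nodes[match(ec, net0$nodes$id), c("x", "y")])^2))
  net1 <- add_water_routes(net0, data.frame(u = wc, v = ec, length_km = len))
  res1 <- run_scenario(net1, scen$polygons, scen$destinations,
                       n_per_polygon = 20, seed = 2)
  expect_gt(res1$summary$reachable_fraction, 0)
  cross <- Filter(function(r) r$nodes[1] %in% west &&
                    r$nodes[length(r$nodes)] %in% east, res1$routes$time)
  expect_gt(length(cross), 0L)
  for (r in cross) expect_true(all(c(wc, ec) %in% r$nodes))

  # cardinality: 1 polygon, 1 destination, k = 1
  res2 <- run_scenario(net1, scen$polygons, scen$destinations[1, ],
                       n_per_polygon = 20, k = 1, seed = 2)
  expect_lte(length(res2$routes$time), res2$origin_set$n_unique)
})
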