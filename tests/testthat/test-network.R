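test_that("water routes are added at dhow speed with exact conversion", {
  nodes <- data.frame(id = c("w", "e"), x = c(0, 74.08), y = 0)
  net <- transport_network(nodes, data.frame(u = character(0), v = character(0),
                                             length_km = numeric(0),
                                             mode = character(0)))
  out <- add_water_routes(net, data.frame(u = "w", v = "e",
                                          length_km = 74.08))
  expect_equal(nrow(out$edges), 2L)  # bidirectional
  expect_equal(unique(out$edges$speed_kmh), 37.04)
  expect_equal(unique(out$edges$time_h), 2, tolerance = 1e-9)
  expect_identical(unique(out$edges$mode), "water")
})

test_that("an empty crossing list leaves the network unchanged", {
  net <- random_network(5, seed = 9)
  out <- add_water_routes(net, data.frame(u = character(0),
                                          v = character(0),
                                          length_km = numeric(0)))
  expect_identical(out$edges, net$edges)
  expect_identical(out$nodes, net$nodes)
})

test_that("unknown crossing endpoints are errors naming the crossing", {
  net <- random_network(4, seed = 1)
  expect_error(add_water_routes(net, data.frame(u = "n01", v = "ghost",
                                                length_km = 5)),
               "ghost")
})

test_that("a two-way chain merges into one edge with summed attributes", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 2, 5), y = 0)
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"),
                      length_km = c(2, 3), speed_kmh = 60,
                      mode = "primary", oneway = FALSE)
  net <- transport_network(nodes, edges)
  simp <- simplify_network(net)
  expect_equal(nrow(simp$network$nodes), 2L)
  e <- simp$network$edges
  expect_equal(nrow(e), 2L)
  expect_equal(unique(e$length_km), 5)
  expect_equal(unique(e$time_h), 5 / 60, tolerance = 1e-12)
  expect_identical(sort(simp$mapping$new_id[simp$mapping$old_id == "b"]),
                   sort(simp$mapping$new_id)[1L])
})

test_that("merged speed is the harmonic combination of segment speeds", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 3), y = 0)
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"),
                      length_km = c(1, 2), speed_kmh = c(30, 90),
                      mode = "primary", oneway = FALSE)
  simp <- simplify_network(transport_network(nodes, edges))
  e <- simp$network$edges
  # total 3 km in 1/30 + 2/90 h
  expect_equal(unique(e$speed_kmh), 3 / (1 / 30 + 2 / 90), tolerance = 1e-9)
})

test_that("one-way chains merge only when direction is consistent", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = 0)
  consistent <- data.frame(u = c("a", "b"), v = c("b", "c"),
                           length_km = 1, speed_kmh = 50,
                           mode = "primary", oneway = TRUE)
  simp <- simplify_network(transport_network(nodes, consistent))
  expect_equal(nrow(simp$network$nodes), 2L)
  expect_true(all(simp$network$edges$oneway))
  # head-to-head one-way edges must NOT merge (no through movement)
  clash <- data.frame(u = c("a", "c"), v = c("b", "b"),
                      length_km = 1, speed_kmh = 50,
                      mode = "primary", oneway = TRUE)
  simp2 <- simplify_network(transport_network(nodes, clash))
  expect_equal(nrow(simp2$network$nodes), 3L)
})

test_that("simplification is a fixpoint on already-simple graphs", {
  net <- random_network(6, p_edge = 0.8, oneway_frac = 0, seed = 4)
  s1 <- simplify_network(net)
  s2 <- simplify_network(s1$network)
  expect_equal(nrow(s2$network$nodes), nrow(s1$network$nodes))
  expect_equal(nrow(s2$network$edges), nrow(s1$network$edges))
})

test_that("generated chains are removed exactly and counts shrink", {
  net <- chained_network(seed = 3, n_chains = 1, chain_nodes = 2)
  # a 2-node interstitial chain: simplification removes exactly those 2
  n_chain_nodes <- sum(grepl("^C", net$nodes$id))
  expect_equal(n_chain_nodes, 2L)
  simp <- simplify_network(net)
  expect_equal(nrow(simp$network$nodes), nrow(net$nodes) - 2L)
  expect_lte(nrow(simp$network$edges), nrow(net$edges))
  expect_false(any(grepl("^C", simp$network$nodes$id)))
})

test_that("simplification preserves shortest distances and times", {
  for (seed in 1:4) {
    net <- chained_network(seed = seed)
    simp <- simplify_network(net)
    kept <- simp$network$nodes$id
    set.seed(seed)
    pairs <- cbind(sample(kept, 6, replace = TRUE),
                   sample(kept, 6, replace = TRUE))
    for (w in c("distance", "time")) {
      for (i in seq_len(nrow(pairs))) {
        r0 <- shortest_path(net, pairs[i, 1], pairs[i, 2], w)
        r1 <- shortest_path(simp$network, pairs[i, 1], pairs[i, 2], w)
        expect_identical(is.null(r0), is.null(r1))
        if (!is.null(r0)) {
          expect_equal(route_cost <- r1$total_km, r0$total_km, tolerance = 1e-6)
          expect_equal(r1$total_h, r0$total_h, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("consolidation collapses close nodes and drops self-loops", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 0.05, 10), y = 0)
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"), length_km = c(0.05, 9.95),
                      speed_kmh = 50, mode = "primary", oneway = FALSE)
  simp <- simplify_network(transport_network(nodes, edges),
                           consolidate_radius_km = 0.1,
                           protect = c("a", "b", "c"))
  expect_equal(nrow(simp$network$nodes), 2L)
  expect_false(any(simp$network$edges$u == simp$network$edges$v))
})

test_that("network statistics count nodes, edges, modes and components", {
  empty <- transport_network(data.frame(id = character(0), x = numeric(0),
                                        y = numeric(0)),
                             data.frame(u = character(0), v = character(0),
                                        length_km = numeric(0),
                                        mode = character(0)))
  st <- network_stats(empty)
  expect_equal(st$n_nodes, 0L)
  expect_equal(st$n_edges, 0L)
  expect_equal(st$n_components, 0L)

  cfg <- synth_config(grid_rows = 16, grid_cols = 16,
                      network_spec = list(nodes_per_side = 3,
                                          n_water_crossings = 0,
                                          n_chains = 0))
  expect_warning(net <- gen_transport_network(cfg), "disconnected")
  st <- network_stats(net)
  expect_equal(st$n_nodes, 18L)  # two 3x3 lattices
  expect_equal(st$n_components, 2L)
  simp <- simplify_network(net)
  expect_lte(network_stats(simp$network)$n_nodes, st$n_nodes)
})
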