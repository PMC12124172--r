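#' Configuration for a synthetic study world
#'
#' Defines the ground-truth world every downstream stage is tested
#' against: a 1-km lattice of environmental covariates, prey species whose
#' occurrence probability is a logistic function of those covariates with a
#' shared sampling-bias gradient, a two-landmass road network with sea
#' crossings, habitat polygons over the truly suitable region, and
#' destination points on the far landmass.
#'
#' @param grid_rows,grid_cols lattice size (>= 8).
#' @param cell_size cell edge, km (default 1, the analysis lattice).
#' @param n_species number of prey species (default 7).
#' @param n_presences presence records sampled per species (default 150;
#'   species are modelled when >100 records are available).
#' @param n_uniform_background uniform random background points generated
#'   alongside the target-group sample for bias comparisons.
#' @param species_response optional list (one named coefficient vector per
#'   species, over layer names); a default with a shared favorable gradient
#'   and per-species idiosyncrasies is built when NULL.
#' @param bias_strength >= 0; sampling probability is multiplied by
#'   `exp(bias_strength * accessibility)` where accessibility is a smooth
#'   gradient shared across all species (so target-group background
#'   cancels it).
#' @param noise_amplitude sd of the additive noise on the gradient layers.
#' @param network_spec list: nodes_per_side, oneway_frac, n_water_crossings,
#'   n_chains, chain_nodes, classes.
#' @param n_destinations destination points on the far landmass (default 34).
#' @param n_polygons habitat polygons (default 2).
#' @param polygon_halfwidth_km half-width of each square habitat polygon.
#' @param seed master seed; every generator derives its stream from it.
#' @return a `synth_config`.
#' @export
synth_config <- function(grid_rows = 64, grid_cols = 64, cell_size = 1,
                         n_species = 7, n_presences = 150,
                         n_uniform_background = 500,
                         species_response = NULL, bias_strength = 0,
                         noise_amplitude = 0.1,
                         network_spec = list(), n_destinations = 34,
                         n_polygons = 2, polygon_halfwidth_km = 4,
                         seed = 1) {
  if (grid_rows < 8 || grid_cols < 8)
    stop("grid_rows and grid_cols must be >= 8")
  if (bias_strength < 0) stop("bias_strength must be >= 0")
  ns_default <- list(nodes_per_side = 5, oneway_frac = 0.15,
                     n_water_crossings = 2, n_chains = 2, chain_nodes = 3,
                     classes = c("primary", "secondary", "tertiary"))
  unknown <- setdiff(names(network_spec), names(ns_default))
  if (length(unknown))
    stop("unknown network_spec key(s): ", paste(unknown, collapse = ", "))
  ns <- utils::modifyList(ns_default, network_spec)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size, n_species = as.integer(n_species),
                 n_presences = as.integer(n_presences),
                 n_uniform_background = as.integer(n_uniform_background),
                 species_response = species_response,
                 bias_strength = bias_strength,
                 noise_amplitude = noise_amplitude,
                 network_spec = ns, n_destinations = as.integer(n_destinations),
                 n_polygons = as.integer(n_polygons),
                 polygon_halfwidth_km = polygon_halfwidth_km,
                 seed = as.integer(seed)),
            class = "synth_config")
}

world_extent <- function(config)
  list(W = config$grid_cols * config$cell_size,
       H = config$grid_rows * config$cell_size)

#' Closed-form trend surfaces of the synthetic gradient layers
#'
#' The gradient layers are these trends plus iid normal noise of sd
#' `noise_amplitude`; with amplitude 0 a layer equals its trend exactly.
#'
#' @param config a `synth_config`.
#' @param layer one of "grad_x", "grad_y", "elev".
#' @return matrix of trend values.
#' @export
trend_surface <- function(config, layer = c("grad_x", "grad_y", "elev")) {
  layer <- match.arg(layer)
  nr <- config$grid_rows; nc <- config$grid_cols
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  switch(layer,
         grad_x = (col - 0.5) / nc,
         grad_y = (row - 0.5) / nr,
         elev = sin(2 * pi * (col - 0.5) / nc) * cos(2 * pi * (row - 0.5) / nr))
}

clamp01 <- function(m) pmin(pmax(m, 0), 1)

#' Generate the synthetic environmental raster stack
#'
#' Seven co-registered 1-km layers: two smooth axis gradients and one
#' sinusoidal elevation-like surface (each trend plus additive noise), two
#' land-cover proportion layers in \[0, 1\], a human-modification layer in
#' \[0, 1\] (high near the "city" corner), and a crop-cover proportion in
#' \[0, 1\].
#'
#' @param config a `synth_config`.
#' @return named list of `raster_grid` layers.
#' @export
gen_environment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  amp <- config$noise_amplitude
  with_seed(config$seed, {
    noise <- function() matrix(stats::rnorm(nr * nc, 0, 1), nr, nc)
    grad_x <- trend_surface(config, "grad_x") + amp * noise()
    grad_y <- trend_surface(config, "grad_y") + amp * noise()
    elev <- trend_surface(config, "elev") + amp * noise()
    lc_grass <- clamp01(stats::plogis(2 * (trend_surface(config, "elev"))) +
                          amp * noise())
    lc_shrub <- clamp01(1 - lc_grass + amp * noise())
    # human modification: strongest near the north-west corner
    col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    row <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    d <- sqrt(((col - 0.5) / nc)^2 + ((row - 0.5) / nr)^2)
    human_mod <- clamp01(stats::plogis(6 * (0.35 - d)) + amp * noise())
    crop <- clamp01(0.6 * stats::plogis(8 * (0.25 - abs(d - 0.45))) +
                      amp * noise())
    mk <- function(m) raster_grid(m, origin_x = 0,
                                  origin_y = nr * config$cell_size,
                                  cell_size = config$cell_size)
    list(grad_x = mk(grad_x), grad_y = mk(grad_y), elev = mk(elev),
         lc_grass = mk(lc_grass), lc_shrub = mk(lc_shrub),
         human_mod = mk(human_mod), crop = mk(crop))
  })
}

# Shared favorable direction (prey concentrate on the western landmass,
# at low grad_x and low human modification) plus two strong per-species idiosyncratic terms, so species
# remain distinguishable against a target-group background.
default_species_response <- function(config, layer_names) {
  idio <- setdiff(layer_names, c("grad_x", "human_mod"))
  lapply(seq_len(config$n_species), function(s) {
    # negative intercept keeps ranges restricted (realistic prevalence ~0.2)
    beta <- c("(Intercept)" = -4, grad_x = -2, human_mod = -1.5)
    a <- idio[(s - 1L) %% length(idio) + 1L]
    b <- idio[s %% length(idio) + 1L]
    beta[a] <- 2
    beta[b] <- -2
    beta
  })
}

#' Shared sampling-bias (accessibility) surface
#'
#' Smooth gradient in \[0, 1\], highest at the north-west corner (the
#' "survey access" corner); the per-cell sampling weight of every species
#' is multiplied by `exp(bias_strength * accessibility)`.
#'
#' @param config a `synth_config`.
#' @return `raster_grid` of accessibility.
#' @export
bias_surface <- function(config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  d <- sqrt(((col - 0.5) / nc)^2 + ((row - 0.5) / nr)^2)
  raster_grid(1 - d / max(d), origin_x = 0,
              origin_y = nr * config$cell_size, cell_size = config$cell_size)
}

standardize_layer <- function(g) {
  v <- g$values
  (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
}

#' True occurrence probability surface for one species
#'
#' `sigmoid(beta . z)` over the standardized covariate layers; the ground
#' truth the species generator samples from (before the bias multiplier).
#'
#' @param stack environment stack from [gen_environment()].
#' @param beta named coefficient vector over layer names.
#' @return `raster_grid` of probabilities in \[0, 1\].
#' @export
true_occurrence_probability <- function(stack, beta) {
  lin <- if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
  for (nm in setdiff(names(beta), "(Intercept)")) {
    if (!nm %in% names(stack)) stop("unknown layer in species response: ", nm)
    lin <- lin + beta[[nm]] * standardize_layer(stack[[nm]])
  }
  if (identical(lin, 0)) lin <- matrix(0, nrow(stack[[1L]]$values),
                                       ncol(stack[[1L]]$values))
  g <- stack[[1L]]
  raster_grid(stats::plogis(lin), g$origin_x, g$origin_y, g$cell_size,
              g$nodata, g$crs_tag)
}

#' Generate biased species occurrence points
#'
#' For each species, `n_presences` presence cells are drawn (with
#' replacement) with probability proportional to
#' `sigmoid(beta . z) * exp(bias_strength * accessibility)`, the bias
#' gradient shared across species (target-group structure); points are
#' jittered uniformly within their cell. A uniform random background sample
#' (`kind == "background"`) is appended for bias-comparison experiments;
#' the target-group background for a species is the presence points of all
#' other species (see [target_group_background()]).
#'
#' @param stack environment stack.
#' @param config a `synth_config`.
#' @return an occurrence set: data.frame(species, x, y, kind).
#' @export
gen_species_occurrences <- function(stack, config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  if (config$n_presences > nr * nc)
    stop("requested presences exceed the number of grid cells")
  responses <- config$species_response %||%
    default_species_response(config, names(stack))
  if (length(responses) != config$n_species)
    stop("species_response must have one coefficient vector per species")
  acc <- bias_surface(config)$values
  cs <- config$cell_size
  with_seed(config$seed + 1L, {
    out <- list()
    for (s in seq_len(config$n_species)) {
      if (config$n_presences == 0L) next
      p <- true_occurrence_probability(stack, responses[[s]])$values
      w <- as.vector(p * exp(config$bias_strength * acc))
      cells <- sample.int(nr * nc, config$n_presences, replace = TRUE,
                          prob = w)
      row <- (cells - 1L) %% nr + 1L
      col <- (cells - 1L) %/% nr + 1L
      x <- (col - 1L) * cs + stats::runif(length(cells)) * cs
      y <- nr * cs - ((row - 1L) * cs + stats::runif(length(cells)) * cs)
      out[[s]] <- data.frame(species = sprintf("species_%02d", s),
                             x = x, y = y, kind = "presence")
    }
    nb <- config$n_uniform_background
    if (nb > 0L)
      out[[length(out) + 1L]] <-
        data.frame(species = NA_character_,
                   x = stats::runif(nb, 0, nc * cs),
                   y = stats::runif(nb, 0, nr * cs),
                   kind = "background")
    if (!length(out))
      return(data.frame(species = character(0), x = numeric(0),
                        y = numeric(0), kind = character(0)))
    do.call(rbind, out)
  })
}

#' Target-group background for one species
#'
#' The presence points of all species except the focal one; the shared
#' sampling bias affects this sample the same way it affects the focal
#' presences, so it cancels in the presence/background contrast.
#'
#' @param occurrences occurrence set from [gen_species_occurrences()].
#' @param species focal species label.
#' @return data.frame(x, y).
#' @export
target_group_background <- function(occurrences, species) {
  tg <- occurrences[occurrences$kind == "presence" &
                      !is.na(occurrences$species) &
                      occurrences$species != species, c("x", "y")]
  rownames(tg) <- NULL
  tg
}

#' Write an occurrence set to CSV (species,x,y,kind)
#' @param occurrences occurrence set data.frame.
#' @param path output file.
#' @return invisibly the path.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.csv(occurrences, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an occurrence CSV written by [write_occurrences()]
#' @param path file path.
#' @return data.frame(species, x, y, kind).
#' @export
read_occurrences <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

#' Generate the two-landmass multimodal transport network
#'
#' Two jittered road lattices ("west" and "east" landmasses) separated by a
#' sea strait, with class-labelled edges at class-default speeds, a
#' configurable fraction of one-way edges, explicit degree-2 chains (to
#' exercise simplification), and `n_water_crossings` dhow-speed water edges
#' joining the landmasses. Edge lengths equal Euclidean node distances.
#' Zero crossings with two landmasses emits a warning (cross-sea routing
#' will be infeasible), not an error.
#'
#' @param config a `synth_config`.
#' @return a `transport_network` (nodes carry a `landmass` column).
#' @export
gen_transport_network <- function(config) {
  ns <- config$network_spec
  ext <- world_extent(config)
  m <- ns$nodes_per_side
  with_seed(config$seed + 2L, {
    lattice <- function(x0, x1, prefix) {
      gx <- seq(x0, x1, length.out = m)
      gy <- seq(0.08 * ext$H, 0.92 * ext$H, length.out = m)
      jit <- 0.15 * min(diff(gx)[1L], diff(gy)[1L])
      nodes <- expand.grid(ix = seq_len(m), iy = seq_len(m))
      nodes$x <- gx[nodes$ix] + stats::runif(nrow(nodes), -jit, jit)
      nodes$y <- gy[nodes$iy] + stats::runif(nrow(nodes), -jit, jit)
      nodes$id <- sprintf("%s%02d%02d", prefix, nodes$ix, nodes$iy)
      nodes
    }
    west <- lattice(0.04 * ext$W, 0.40 * ext$W, "W")
    east <- lattice(0.60 * ext$W, 0.96 * ext$W, "E")
    mk_edges <- function(nodes) {
      e <- list()
      for (i in seq_len(nrow(nodes))) {
        for (d in list(c(1L, 0L), c(0L, 1L))) {
          jx <- nodes$ix[i] + d[1L]; jy <- nodes$iy[i] + d[2L]
          j <- which(nodes$ix == jx & nodes$iy == jy)
          if (!length(j)) next
          e[[length(e) + 1L]] <- data.frame(u = nodes$id[i], v = nodes$id[j])
        }
      }
      do.call(rbind, e)
    }
    edges <- rbind(mk_edges(west), mk_edges(east))
    nodes <- rbind(cbind(west[, c("id", "x", "y")], landmass = "west"),
                   cbind(east[, c("id", "x", "y")], landmass = "east"))
    edges$mode <- sample(ns$classes, nrow(edges), replace = TRUE)
    edges$oneway <- stats::runif(nrow(edges)) < ns$oneway_frac
    # subdivide a few west two-way edges into degree-2 chains
    chain_pool <- which(!edges$oneway & grepl("^W", edges$u))
    chain_sel <- utils::head(chain_pool, ns$n_chains)
    extra_nodes <- list(); extra_edges <- list()
    for (ci in seq_along(chain_sel)) {
      er <- edges[chain_sel[ci], ]
      a <- nodes[nodes$id == er$u, ]; b <- nodes[nodes$id == er$v, ]
      kk <- ns$chain_nodes
      tt <- seq_len(kk) / (kk + 1)
      ids <- sprintf("C%02d%02d", ci, seq_len(kk))
      extra_nodes[[ci]] <- data.frame(id = ids,
                                      x = a$x + tt * (b$x - a$x),
                                      y = a$y + tt * (b$y - a$y),
                                      landmass = a$landmass)
      seq_ids <- c(er$u, ids, er$v)
      extra_edges[[ci]] <- data.frame(u = seq_ids[-length(seq_ids)],
                                      v = seq_ids[-1L],
                                      mode = er$mode, oneway = FALSE)
    }
    if (length(chain_sel)) {
      edges <- edges[-chain_sel, , drop = FALSE]
      nodes <- rbind(nodes, do.call(rbind, extra_nodes))
      edges <- rbind(edges, do.call(rbind, extra_edges))
    }
    dist_for <- function(e) {
      ui <- match(e$u, nodes$id); vi <- match(e$v, nodes$id)
      sqrt((nodes$x[ui] - nodes$x[vi])^2 + (nodes$y[ui] - nodes$y[vi])^2)
    }
    edges$length_km <- dist_for(edges)
    edges$speed_kmh <- class_default_speeds()[edges$mode]
    net <- transport_network(nodes, edges)
    if (ns$n_water_crossings == 0L) {
      warning("no water crossings: the two landmasses are disconnected and cross-sea routing will be infeasible")
      return(net)
    }
    wcoast <- west[order(-west$x), ][seq_len(ns$n_water_crossings), ]
    ecoast <- east[order(east$x), ][seq_len(ns$n_water_crossings), ]
    crossings <- data.frame(u = wcoast$id, v = ecoast$id,
                            length_km = sqrt((wcoast$x - ecoast$x)^2 +
                                               (wcoast$y - ecoast$y)^2))
    add_water_routes(net, crossings, speed_knots = 20)
  })
}

#' Generate habitat polygons and destination points for a scenario
#'
#' Square habitat polygons are centered on the highest true-suitability
#' cells of the west landmass (true suitability: the shared favorable
#' response `sigmoid(-2 z(grad_x) - 1.5 z(human_mod))`), so polygon interiors
#' sit in the top of the truth distribution. Destination points (default
#' 34) are jittered around road nodes of the east landmass.
#'
#' @param stack environment stack.
#' @param network network from [gen_transport_network()].
#' @param config a `synth_config`.
#' @return list: `polygons`, `destinations` (data.frame id, x, y),
#'   `truth` (`raster_grid`).
#' @export
gen_scenario <- function(stack, network, config) {
  ext <- world_extent(config)
  hw <- config$polygon_halfwidth_km
  if ((2 * hw)^2 < config$cell_size^2)
    stop("polygon area smaller than one grid cell")
  truth <- true_occurrence_probability(stack,
                                       c(grad_x = -2, human_mod = -1.5))
  cc <- cell_centers(truth)
  west_cells <- cc[cc$x < 0.5 * ext$W, ]
  with_seed(config$seed + 3L, {
    polys <- list()
    taken <- west_cells[0, ]
    cand <- west_cells[order(-west_cells$value), ]
    for (i in seq_len(config$n_polygons)) {
      if (!nrow(cand)) break
      ctr <- cand[1L, ]
      x0 <- max(ctr$x - hw, 0); x1 <- min(ctr$x + hw, 0.5 * ext$W)
      y0 <- max(ctr$y - hw, 0); y1 <- min(ctr$y + hw, ext$H)
      ring <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      polys[[i]] <- list(id = sprintf("habitat_%d", i), rings = list(ring))
      # keep later polygons away from this one
      far <- sqrt((cand$x - ctr$x)^2 + (cand$y - ctr$y)^2) > 3 * hw
      cand <- cand[far, ]
    }
    east_nodes <- network$nodes[network$nodes$landmass == "east", ]
    if (!nrow(east_nodes)) east_nodes <- network$nodes
    pick <- sample.int(nrow(east_nodes), config$n_destinations, replace = TRUE)
    dest <- data.frame(id = sprintf("dest_%02d", seq_len(config$n_destinations)),
                       x = east_nodes$x[pick] + stats::runif(config$n_destinations, -0.5, 0.5),
                       y = east_nodes$y[pick] + stats::runif(config$n_destinations, -0.5, 0.5))
    list(polygons = polys, destinations = dest, truth = truth)
  })
}
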