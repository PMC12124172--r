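make_layer <- function(m) raster_grid(m)

test_that("correlated layer pairs are pruned at |r| > 0.7", {
  set.seed(1)
  base <- matrix(rnorm(100), 10, 10)
  noisy <- base + matrix(rnorm(100, sd = 0.4), 10, 10)   # |r| ~ 0.9
  indep <- matrix(rnorm(100), 10, 10)
  st <- list(A = make_layer(base), B = make_layer(noisy),
             C = make_layer(indep))
  out <- prune_correlated(st, method = "pearson")
  expect_length(out$stack, 2L)
  expect_true("C" %in% names(out$stack))
  expect_equal(nrow(out$report), 1L)
  # oracle: recompute the full matrix on the survivors by brute force
  vals <- sapply(out$stack, function(g) as.vector(g$values))
  cm <- abs(stats::cor(vals, method = "pearson")); diag(cm) <- 0
  expect_lte(max(cm), 0.7)
})

test_that("single layers and constant layers are handled", {
  single <- list(A = make_layer(matrix(rnorm(64), 8, 8)))
  expect_identical(names(prune_correlated(single)$stack), "A")
  with_const <- c(single, list(K = make_layer(matrix(1, 8, 8))))
  expect_warning(out <- prune_correlated(with_const), "constant")
  expect_identical(names(out$stack), "A")
  expect_true("K" %in% out$report$dropped)
})

test_that("pruned stacks never violate the threshold (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(rnorm(64), 8, 8)
    st <- lapply(1:6, function(i)
      make_layer(base * runif(1, 0, 1.5) + matrix(rnorm(64, sd = 1), 8, 8)))
    names(st) <- paste0("L", 1:6)
    out <- prune_correlated(st, method = "spearman")
    if (length(out$stack) >= 2L) {
      vals <- sapply(out$stack, function(g) as.vector(g$values))
      cm <- abs(stats::cor(vals, method = "spearman")); diag(cm) <- 0
      expect_lte(max(cm), 0.7)
    }
  }
})

test_that("background features standardize to mean 0 sd 1", {
  set.seed(2)
  bg <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  spec <- feature_spec(bg)
  Fb <- featurize(spec, bg)
  expect_lt(max(abs(colMeans(Fb))), 1e-8)
  expect_lt(max(abs(apply(Fb, 2, sd) - 1)), 1e-8)
  expect_error(featurize(spec, matrix(0, 2, 1, dimnames = list(NULL, "a"))),
               "missing covariate")
})

test_that("null presences shrink all weights toward zero", {
  cfg <- synth_config(grid_rows = 48, grid_cols = 48, n_species = 1,
                      n_presences = 2000, n_uniform_background = 2000,
                      species_response = list(c(grad_x = 0)),
                      bias_strength = 0, seed = 31)
  st <- gen_environment(cfg)
  occ <- gen_species_occurrences(st, cfg)
  pres <- occ[occ$kind == "presence", c("x", "y")]
  bg <- occ[occ$kind == "background", c("x", "y")]
  m <- fit_maxent(pres, bg, st, species = "null")
  expect_true(all(abs(m$weights) < 0.05))
})

test_that("1-D fits match an independent grid-search of the objective", {
  # single-gradient world, presences concentrated at high values
  set.seed(7)
  g <- raster_grid(matrix(rep(seq(0, 1, length.out = 30), each = 30), 30, 30))
  st <- list(grad = g)
  cc <- cell_centers(g)
  w_true <- exp(3 * cc$value)
  pres_cells <- sample(nrow(cc), 300, replace = TRUE, prob = w_true)
  bg_cells <- sample(nrow(cc), 1000, replace = TRUE)
  pres <- data.frame(x = cc$x[pres_cells], y = cc$y[pres_cells])
  bg <- data.frame(x = cc$x[bg_cells], y = cc$y[bg_cells])
  m <- fit_maxent(pres, bg, st, transforms = "linear")
  expect_gt(m$weights[1L], 0)
  # oracle: coarse-to-fine grid search over the same penalized objective
  Fp <- featurize(m$feature_spec,
                  extract_stack_at(st, pres$x, pres$y))
  Fb <- featurize(m$feature_spec, extract_stack_at(st, bg$x, bg$y))
  lam <- m$beta * m$lambda
  obj <- function(w) {
    s <- Fb * w
    -mean(Fp * w) + log(mean(exp(s))) + lam * abs(w)
  }
  ws <- seq(-5, 5, by = 1e-3)
  best <- ws[which.min(vapply(ws, obj, 0))]
  expect_equal(obj(m$weights[1L]), obj(best), tolerance = 1e-3)
  expect_equal(unname(m$weights[1L]), best, tolerance = 1e-2)
})

test_that("doubling beta never increases the L1 norm of the weights", {
  cfg <- synth_config(grid_rows = 24, grid_cols = 24, n_species = 1,
                      n_presences = 200, n_uniform_background = 500,
                      bias_strength = 0, seed = 13)
  st <- gen_environment(cfg)
  occ <- gen_species_occurrences(st, cfg)
  pres <- occ[occ$kind == "presence", c("x", "y")]
  bg <- occ[occ$kind == "background", c("x", "y")]
  l1 <- vapply(c(1, 2, 4, 8), function(b)
    sum(abs(fit_maxent(pres, bg, st, beta = b)$weights)), 0)
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("too few presences refuse to fit, flagged unmodelled", {
  st <- list(a = make_layer(matrix(rnorm(64), 8, 8)))
  pres <- data.frame(x = runif(5, 0, 8), y = runif(5, 0, 8))
  bg <- data.frame(x = runif(50, 0, 8), y = runif(50, 0, 8))
  expect_warning(m <- fit_maxent(pres, bg, st), "not modelled")
  expect_true(m$unmodelled)
})

test_that("model scores normalize to mean 1 over background", {
  cfg <- synth_config(grid_rows = 16, grid_cols = 16, n_species = 2,
                      n_presences = 100, seed = 17)
  st <- gen_environment(cfg)
  occ <- gen_species_occurrences(st, cfg)
  pres <- occ[occ$kind == "presence" & occ$species %in% "species_01",
              c("x", "y")]
  bg <- target_group_background(occ, "species_01")
  m <- fit_maxent(pres, bg, st)
  sb <- score_points(m, extract_stack_at(st, bg$x, bg$y))
  expect_equal(mean(sb), 1, tolerance = 1e-6)
})

test_that("suitability maps are monotone transforms at fixed prevalence", {
  cfg <- synth_config(grid_rows = 16, grid_cols = 16, n_species = 1,
                      n_presences = 150, n_uniform_background = 400,
                      bias_strength = 0, seed = 19)
  st <- gen_environment(cfg)
  occ <- gen_species_occurrences(st, cfg)
  m <- fit_maxent(occ[occ$kind == "presence", c("x", "y")],
                  occ[occ$kind == "background", c("x", "y")], st)
  suit <- predict_suitability(m, st)
  expect_true(all(suit$values >= 0 & suit$values <= 1, na.rm = TRUE))
  cc <- cell_centers(st[[1]])
  raw <- score_points(m, extract_stack_at(st, cc$x, cc$y))
  expect_equal(order(raw), order(as.vector(suit$values)))
  # all-zero weights: flat map at the prevalence constant
  m0 <- m; m0$weights[] <- 0; m0$log_partition <- 0; m0$background_raw <- 1
  flat <- predict_suitability(m0, st)
  expect_true(all(abs(flat$values - 0.5) < 1e-12))
})

test_that("suitability values match the hand-computed transform", {
  # 5-cell fixture with fixed weights
  g <- raster_grid(matrix(c(0, 0.25, 0.5, 0.75, 1), 1, 5))
  st <- list(v = g)
  spec <- structure(list(covariates = "v", transforms = "linear",
                         feature_names = "v", mean = c(v = 0.5),
                         sd = c(v = 0.25)), class = "feature_spec")
  m <- structure(list(weights = 0.8, feature_spec = spec, log_partition = 0.1,
                      background_raw = 1, unmodelled = FALSE),
                 class = "sdm_model")
  out <- predict_suitability(m, st, prevalence = 0.5)
  z <- (c(0, 0.25, 0.5, 0.75, 1) - 0.5) / 0.25
  s <- exp(0.8 * z - 0.1)
  expect_equal(as.vector(out$values), s / (1 + s), tolerance = 1e-9)
})

test_that("beta tuning reduces the train-test gap on overfit fixtures", {
  # many covariates, few presences: classic overfit regime
  set.seed(23)
  st <- lapply(1:8, function(i) make_layer(matrix(rnorm(900), 30, 30)))
  names(st) <- paste0("r", 1:8)
  cc <- cell_centers(st[[1]])
  pres_cells <- sample(nrow(cc), 25)
  pres <- data.frame(x = cc$x[pres_cells], y = cc$y[pres_cells])
  bgc <- sample(nrow(cc), 500, replace = TRUE)
  bg <- data.frame(x = cc$x[bgc], y = cc$y[bgc])
  m <- tune_beta(pres, bg, st, overfit_gap = 0.02, seed = 3)
  h <- m$beta_history
  if (nrow(h) > 1L) {
    expect_gt(m$beta, 1)
    expect_lte(h$gap[nrow(h)], h$gap[1L])
  }
  # an already-good model is returned unchanged at beta 1
  cfg <- synth_config(grid_rows = 24, grid_cols = 24, n_species = 1,
                      n_presences = 400, n_uniform_background = 800,
                      bias_strength = 0, seed = 29)
  env <- gen_environment(cfg)
  occ <- gen_species_occurrences(env, cfg)
  good <- tune_beta(occ[occ$kind == "presence", c("x", "y")],
                    occ[occ$kind == "background", c("x", "y")], env, seed = 1)
  expect_equal(good$beta, 1)
  expect_equal(nrow(good$beta_history), 1L)
})

test_that("richness ensembles sum binary grids and validate inputs", {
  b <- function(v) raster_grid(matrix(v, 2, 2))
  r <- build_richness(list(b(c(1, 1, 0, NA)), b(c(1, 0, 0, 1)),
                           b(c(0, 1, 0, 1))))
  expect_equal(as.vector(r$values), c(2, 2, 0, NA))
  expect_error(build_richness(list(b(c(0.5, 0, 0, 0)))), "not binary")
  seven <- build_richness(replicate(7, b(c(1, 1, 1, 1)), simplify = FALSE))
  expect_true(all(seven$values <= 7))
  zero <- build_richness(replicate(3, b(c(0, 0, 0, 0)), simplify = FALSE))
  expect_true(all(zero$values == 0))
})
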