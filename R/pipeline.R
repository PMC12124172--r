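#' Build a validated pipeline configuration
#'
#' Defaults carry the method's standard settings: correlation prune at
#' |r| > 0.7 (Spearman), beta multiplier 1 with overfit-gap tuning, maxSSS
#' binarization, human-modification mask at 0.25, crop mask at 0.10, HSI
#' core cutoff 4 with a 90% KDE isopleth, ~100 origin points per polygon,
#' 34 destinations, dhow water speed 20 knots, 8-h travel-day isochrone
#' bins. Unknown keys are rejected.
#'
#' @param config list (possibly nested) or path to a YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    synth = list(),  # passed to synth_config()
    stages = list(sdm = TRUE, hsi = TRUE),
    polygons_path = NULL,  # user-supplied origin polygons (GeoJSON)
    prune = list(threshold = 0.7, method = "spearman"),
    sdm = list(split = 0.3, overfit_gap = 0.05, prevalence = 0.5),
    hsi = list(hm_limit = 0.25, crop_limit = 0.10, cutoff = 4,
               isopleth = 0.90),
    network = list(consolidate_radius_km = 0),
    scenario = list(n_per_polygon = 100, k = 1, dhow_knots = 20,
                    bin_hours = 8)
  )
  check_keys <- function(given, known, where) {
    unknown <- setdiff(names(given), names(known))
    if (length(unknown))
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")))
  }
  check_keys(config, defaults, "config")
  for (sec in c("stages", "prune", "sdm", "hsi", "network", "scenario"))
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], defaults[[sec]], sec)
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full stepwise pipeline
#'
#' Synthetic world -> prey SDMs -> richness -> HSI + core habitat ->
#' network simplification -> routing scenarios, each stage reading only the
#' previous stage's serialized outputs under `outdir`. Two source scenarios
#' are routed: the known habitat polygons and the HSI-derived core-habitat
#' polygons. Identical config + seed yields byte-identical artifacts; a
#' reproducibility manifest (config hash, seed, versions, per-file
#' checksums) is written last.
#'
#' @param config a `pipeline_config` (or list/YAML path accepted by
#'   [pipeline_config()]).
#' @param outdir artifact directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  p <- function(...) file.path(outdir, ...)

  # ---- stage 1: synthetic world -----------------------------------------
  scfg <- stage("synth", do.call(synth_config,
                                 c(config$synth, list(seed = config$seed))))
  stage("synth", {
    stack <- gen_environment(scfg)
    write_raster(stack, p("environment.stack.json"))
    occ <- gen_species_occurrences(stack, scfg)
    write_occurrences(occ, p("occurrences.csv"))
    network <- gen_transport_network(scfg)
    write_network(network, p("network.graphml"))
    scen <- gen_scenario(stack, network, scfg)
    write_geojson_polygons(scen$polygons, p("known_habitat.geojson"))
    write_geojson_points(scen$destinations, p("destinations.geojson"))
    write_raster(scen$truth, p("true_suitability.asc"))
  })

  # ---- stage 2: prey SDMs -> richness -----------------------------------
  species_reports <- list()
  if (isTRUE(config$stages$sdm)) stage("sdm", {
    stack <- read_raster(p("environment.stack.json"))
    occ <- read_occurrences(p("occurrences.csv"))
    pruned <- prune_correlated(stack, config$prune$threshold,
                               config$prune$method)
    species <- sort(unique(occ$species[occ$kind == "presence" &
                                         !is.na(occ$species)]))
    binaries <- list()
    for (sp in species) {
      pres <- occ[occ$kind == "presence" & !is.na(occ$species) &
                    occ$species == sp, c("x", "y")]
      bg <- target_group_background(occ, sp)
      model <- tune_beta(pres, bg, pruned$stack, split = config$sdm$split,
                         overfit_gap = config$sdm$overfit_gap,
                         seed = config$seed, species = sp)
      if (isTRUE(model$unmodelled)) {
        species_reports[[sp]] <- list(species = sp, unmodelled = TRUE)
        next
      }
      suit <- predict_suitability(model, pruned$stack,
                                  prevalence = config$sdm$prevalence)
      # threshold on the logistic scale (monotone in the raw score)
      thr_raw <- model$threshold_maxsss
      cscale <- logistic_scale(model, config$sdm$prevalence)
      thr <- cscale * thr_raw / (1 + cscale * thr_raw)
      bin <- binarize_suitability(suit, thr)
      write_raster(suit, p(sprintf("suitability_%s.asc", sp)))
      write_raster(bin, p(sprintf("binary_%s.asc", sp)))
      binaries[[sp]] <- bin
      species_reports[[sp]] <- list(
        species = sp, beta = model$beta,
        auc_train = model$auc_train, auc_test = model$auc_test,
        threshold = thr, overfit_flag = isTRUE(model$overfit_flag),
        weights = as.list(stats::setNames(model$weights,
                                          model$feature_spec$feature_names)),
        dropped_covariates = pruned$report$dropped)
    }
    jsonlite::write_json(species_reports, p("sdm_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    richness <- build_richness(binaries)
    write_raster(richness, p("richness.asc"))
  })

  # ---- stage 3: HSI + core habitat --------------------------------------
  if (isTRUE(config$stages$hsi) && isTRUE(config$stages$sdm)) stage("hsi", {
    richness <- read_raster(p("richness.asc"))
    stack <- read_raster(p("environment.stack.json"))
    hsi <- apply_mask_rules(richness, stack$human_mod, stack$crop,
                            hm_limit = config$hsi$hm_limit,
                            crop_limit = config$hsi$crop_limit)
    write_raster(hsi, p("hsi.asc"))
    core <- extract_core_habitat(hsi, cutoff = config$hsi$cutoff,
                                 isopleth = config$hsi$isopleth)
    for (i in seq_along(core$polygons))
      core$polygons[[i]]$properties <-
        list(isopleth = core$isopleth_level,
             kde_bandwidth_km = core$kde_bandwidth,
             source_cells = core$source_cell_count)
    write_geojson_polygons(core$polygons, p("core_habitat.geojson"))
  })

  # ---- stage 4: network simplification ----------------------------------
  stage("network", {
    network <- read_network(p("network.graphml"))
    simp <- simplify_network(network,
                             consolidate_radius_km = config$network$consolidate_radius_km)
    write_network(simp$network, p("network_simplified.graphml"))
    utils::write.csv(simp$mapping, p("simplification_mapping.csv"),
                     row.names = FALSE, quote = FALSE)
    st_pre <- network_stats(network); st_post <- network_stats(simp$network)
    jsonlite::write_json(list(original = st_pre, simplified = st_post),
                         p("network_stats.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  # ---- stage 5: routing scenarios ---------------------------------------
  stage("scenario", {
    network <- read_network(p("network_simplified.graphml"))
    destinations <- read_geojson_points(p("destinations.geojson"))
    sources <- list()
    if (!is.null(config$polygons_path))
      sources$user <- read_geojson_polygons(config$polygons_path)
    else
      sources$known <- read_geojson_polygons(p("known_habitat.geojson"))
    if (isTRUE(config$stages$hsi) && isTRUE(config$stages$sdm) &&
        file.exists(p("core_habitat.geojson")))
      sources$hsi <- read_geojson_polygons(p("core_habitat.geojson"))
    summaries <- list()
    for (src in names(sources)) {
      res <- run_scenario(network, sources[[src]], destinations,
                          n_per_polygon = config$scenario$n_per_polygon,
                          k = config$scenario$k, seed = config$seed)
      for (wt in c("distance", "time"))
        write_routes(res$routes[[wt]], network,
                     p(sprintf("routes_%s_%s.geojson", src, wt)))
      utils::write.csv(res$node_load$bottlenecks,
                       p(sprintf("bottlenecks_%s.csv", src)),
                       row.names = FALSE, quote = FALSE)
      summaries[[src]] <- res$summary
    }
    if (nrow(destinations)) {
      anchor <- snap_to_network(destinations[1L, , drop = FALSE],
                                network)$unique_nodes[1L]
      iso <- isochrone(network, anchor,
                       bin_hours = config$scenario$bin_hours)
      utils::write.csv(iso, p("isochrone.csv"), row.names = FALSE,
                       quote = FALSE)
    }
    jsonlite::write_json(summaries, p("scenario_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  # ---- manifest ---------------------------------------------------------
  cfg_path <- p("config_used.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(utils::packageVersion("wildroute")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
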