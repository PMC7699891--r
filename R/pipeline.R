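## End-to-end orchestration: synthesize (or load) a region, fit the
## transition model and suitability surfaces, allocate the scenarios,
## evaluate the six services per map, standardize jointly, sum, correlate,
## and record every artifact in a manifest.

#' Pipeline configuration
#'
#' @param spec A `synthetic_spec` describing the region (synthetic runs).
#' @param scenarios Character vector among "bau", "elp", "rud", or a named
#'   list of `scenario_config` objects.
#' @param weights Service weights (default [default_weights()]).
#' @param n_points Sample points for the correlations (default 2000,
#'   reduced to the valid-cell count if smaller).
#' @param cor_method "spearman" (default) or "pearson".
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @param suit_model Suitability model, "nnet" (default) or "multinom".
#' @param sample_frac Training fraction for the suitability model.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(spec = synthetic_spec(), scenarios = c("bau", "elp", "rud"),
                            weights = default_weights(), n_points = 2000,
                            cor_method = "spearman", seed = 1L,
                            suit_model = "nnet", sample_frac = 0.1) {
  if (is.character(scenarios)) {
    nm <- tolower(scenarios)
    if (anyDuplicated(nm)) stop("scenario names must be unique")
    scenarios <- stats::setNames(lapply(nm, function(s) {
      switch(s, bau = scenario_bau(), elp = NULL, rud = scenario_rud(),
             stop("unknown scenario shorthand: ", s))
    }), toupper(nm))
    # ELP needs the region's reserve mask; built at run time
  } else if (anyDuplicated(names(scenarios))) {
    stop("scenario names must be unique")
  }
  structure(
    list(spec = spec, scenarios = scenarios, weights = weights,
         n_points = n_points, cor_method = cor_method, seed = as.integer(seed),
         suit_model = suit_model, sample_frac = sample_frac),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `shape`, `cell_size`, `seed`, `scenarios`, `n_points`,
#' `cor_method`, `suit_model`, `sample_frac`, `autocorr`, `relief`.
#' Unlisted keys fall back to the [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y[intersect(names(y), c("shape", "cell_size", "autocorr",
                                       "relief", "seed"))]
  spec <- do.call(synthetic_spec, spec_args)
  args <- y[intersect(names(y), c("scenarios", "n_points", "cor_method",
                                  "seed", "suit_model", "sample_frac"))]
  args$spec <- spec
  do.call(pipeline_config, args)
}

# Default ELP reserve mask for a synthetic region: high-suitability forest
# core (upper elevation half of the forest), water bodies (reservoirs) and
# a basic-farmland core (upper half of cultivated by ... elevation-low).
elp_reserve_mask <- function(region) {
  lu <- region$t1$grid
  z <- region$dem$grid
  mask <- matrix(FALSE, nrow(lu), ncol(lu))
  forest <- lu == landuse_classes[["forest"]]
  if (any(forest)) mask[forest & z >= stats::median(z[forest])] <- TRUE
  mask[lu == landuse_classes[["water"]]] <- TRUE
  cult <- lu == landuse_classes[["cultivated"]]
  if (any(cult)) mask[cult & z <= stats::median(z[cult])] <- TRUE
  mask
}

# Basic-farmland mask used by the RUD scenario.
rud_farmland_mask <- function(region) {
  lu <- region$t1$grid
  z <- region$dem$grid
  mask <- matrix(FALSE, nrow(lu), ncol(lu))
  cult <- lu == landuse_classes[["cultivated"]]
  if (any(cult)) mask[cult & z <= stats::median(z[cult])] <- TRUE
  mask
}

#' Evaluate all six ecosystem services for one land-use map
#'
#' @param lu A `land_raster`.
#' @param region A synthetic region (supplies climate, soil, terrain,
#'   districts and tables).
#' @param flow Optional pre-built `flow_graph` (shared across maps since
#'   the terrain is fixed).
#' @param ref_lu Baseline map for the crop-production scaling.
#' @return List of the six service results (each `list(raster, ...)`) plus
#'   the water-yield result under `yield`.
#' @export
evaluate_services <- function(lu, region, flow = NULL, ref_lu = NULL) {
  tab <- region$tables$biophys
  if (is.null(flow)) flow <- build_flow_graph(region$dem)
  wy <- water_yield(region$precip, region$pet, lu, tab)
  list(
    CS = carbon_storage(lu, tab),
    FR = flood_regulation(wy$raster),
    SC = soil_conservation(region$erosivity, region$erodibility, region$dem,
                           lu, tab, flow = flow),
    WP = nitrogen_export(lu, tab, flow, wy$raster),
    HQ = habitat_quality(lu, tab, region$tables$threats),
    CP = crop_production(region$tables$districts, region$districts, lu,
                         ref_lu = ref_lu),
    yield = wy
  )
}

#' Run the full scenario pipeline
#'
#' Generates the synthetic region, fits the transition matrix on the
#' observed pair, trains suitability surfaces on the later map, allocates
#' every scenario to its projected demand, evaluates the six services for
#' the baseline and every scenario map, standardizes all surfaces over
#' joint extremes, computes the summed indicator and the trade-off
#' correlations, and (optionally) writes every artifact plus a JSON
#' manifest with md5 hashes. Reruns with the same config are
#' bit-identical.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (`NULL` = nothing written).
#' @return A `pipeline_run`: list with `region`, `transition`, `demand`,
#'   `maps`, `services`, `standardized`, `ses`, `correlations`, `fom`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  region <- synth_region(config$spec)
  trans <- fit_transition(region$t0, region$t1)
  suit <- fit_suitability(region$t1, region$drivers, model = config$suit_model,
                          sample_frac = config$sample_frac,
                          seed = stage_seed(config$seed, "suitability"))
  flow <- build_flow_graph(region$dem)

  # model validation: reallocate the observed interval and score it
  suit0 <- fit_suitability(region$t0, region$drivers, model = config$suit_model,
                           sample_frac = config$sample_frac,
                           seed = stage_seed(config$seed, "suitability_t0"))
  demand_obs <- class_areas(region$t1)
  sim_t1 <- allocate_ca(region$t0, suit0, demand_obs,
                        seed = stage_seed(config$seed, "validate"))
  fom <- figure_of_merit(region$t0, region$t1, sim_t1)
  fom$baseline <- random_baseline_fom(region$t0, region$t1,
                                      seed = stage_seed(config$seed, "baseline"))

  scen <- config$scenarios
  if ("ELP" %in% names(scen) && is.null(scen[["ELP"]])) {
    sc <- scenario_elp(elp_reserve_mask(region))
    # every water cell is frozen as a reservoir, so water demand cannot
    # fall below the current water area
    a <- class_areas(region$t1)
    sc$demand_floor["water"] <- a[["water"]] / sum(a)
    scen[["ELP"]] <- sc
  }
  if (!is.null(scen[["RUD"]])) {
    if (is.null(scen[["RUD"]]$restriction_mask)) {
      scen[["RUD"]]$restriction_mask <- rud_farmland_mask(region)
    }
  }
  demand <- lapply(scen, function(s) project_demand(region$t1, trans, s))
  maps <- list(baseline = region$t1)
  for (nm in names(scen)) {
    sc <- if (is.null(scen[[nm]])) scenario_bau() else scen[[nm]]
    maps[[nm]] <- allocate_ca(region$t1, suit, demand[[nm]], sc,
                              seed = stage_seed(config$seed, paste0("alloc_", nm)))
  }

  services <- lapply(maps, evaluate_services, region = region, flow = flow,
                     ref_lu = region$t1)

  # joint flood-regulation scale: renormalize FR over all maps' yields
  y_ext <- joint_extremes(lapply(services, function(s) s$yield$raster))
  for (nm in names(services)) {
    services[[nm]]$FR <- flood_regulation(services[[nm]]$yield$raster,
                                          extremes = y_ext)
  }

  six <- c("CS", "FR", "SC", "WP", "HQ", "CP")
  extremes <- lapply(six, function(sv) {
    joint_extremes(lapply(services, function(s) s[[sv]]$raster))
  })
  names(extremes) <- six
  standardized <- lapply(services, function(s) {
    out <- lapply(six, function(sv) standardize(s[[sv]]$raster, extremes[[sv]]))
    names(out) <- six
    out
  })
  ses <- lapply(standardized, ses_surface, weights = config$weights)
  correlations <- lapply(names(standardized), function(nm) {
    pts <- sample_points(standardized[[nm]],
                         n = min(config$n_points,
                                 sum(!is.na(ses[[nm]]$raster$grid))),
                         seed = stage_seed(config$seed, paste0("pts_", nm)))
    list(points = pts,
         spearman = correlate_services(pts, "spearman"),
         pearson = correlate_services(pts, "pearson"))
  })
  names(correlations) <- names(standardized)

  run <- structure(
    list(config = config, region = region, transition = trans,
         demand = demand, maps = maps, services = services,
         standardized = standardized, ses = ses,
         correlations = correlations, fom = fom, manifest = NULL),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

# FoM of a label-preserving random reallocation (same class counts as t1,
# uniformly shuffled over the changed cells' positions): the no-skill
# reference for the self-validation loop.
random_baseline_fom <- function(t0, t1, seed = 1L) {
  set.seed(stage_seed(seed, "random_fom"))
  g0 <- t0$grid
  sim <- g0
  chg <- which(g0 != t1$grid)
  # allocate the same number of changed cells at random positions with the
  # same target-class composition
  pos <- sample(which(valid_mask(t0)), length(chg))
  sim[pos] <- t1$grid[chg]
  sim_r <- land_raster(sim, t0$cell_size, t0$origin, t0$nodata, t0$classes)
  figure_of_merit(t0, t1, sim_r)$fom
}

#' Write a pipeline run to disk with a hashed manifest
#'
#' Land-use maps and service surfaces go out as ESRI ASCII grids, tables
#' and correlation matrices as CSV, and the manifest (parameters + md5 per
#' artifact) as JSON.
#'
#' @param run A `pipeline_run`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly written to `manifest.json`.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)
  for (nm in names(run$maps)) {
    put(run$maps[[nm]], paste0("lu_", tolower(nm), ".asc"), write_ascii_grid)
  }
  for (nm in names(run$services)) {
    for (sv in c("CS", "FR", "SC", "WP", "HQ", "CP")) {
      put(run$services[[nm]][[sv]]$raster,
          paste0(sv, "_", tolower(nm), ".asc"), write_ascii_grid)
    }
    put(run$ses[[nm]]$raster, paste0("ses_", tolower(nm), ".asc"),
        write_ascii_grid)
    put(run$correlations[[nm]]$spearman$r,
        paste0("cor_spearman_", tolower(nm), ".csv"),
        function(x, p) utils::write.csv(as.data.frame(x), p))
  }
  put(as.data.frame(unclass(run$transition)), "transition.csv", csv)
  put(report_run(run)$areas, "class_areas.csv", csv)
  put(report_run(run)$ses_means, "ses_means.csv", csv)
  manifest <- list(
    seed = run$config$seed,
    shape = run$region$spec$shape,
    scenarios = names(run$maps),
    n_points = run$config$n_points,
    fom = run$fom$fom,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Summary tables for a pipeline run
#'
#' Class-area change per scenario, per-service totals (and means for the
#' dimensionless services) with percent change against the baseline map,
#' the summed-indicator means, and the correlation matrices.
#'
#' @param run A `pipeline_run`.
#' @return List of data frames: `areas`, `service_totals`, `ses_means`,
#'   plus `correlations` (list of matrices).
#' @export
report_run <- function(run) {
  maps <- run$maps
  areas <- do.call(rbind, lapply(names(maps), function(nm) {
    a <- class_areas(maps[[nm]])
    data.frame(map = nm, class = names(a), area_km2 = as.numeric(a))
  }))
  base <- areas[areas$map == "baseline", ]
  areas$change_km2 <- areas$area_km2 -
    base$area_km2[match(areas$class, base$class)]

  tot <- function(s, nm) {
    switch(nm,
           CS = s$CS$total, SC = s$SC$total, WP = s$WP$total,
           CP = s$CP$total, FR = s$FR$mean, HQ = s$HQ$mean)
  }
  six <- c("CS", "FR", "SC", "WP", "HQ", "CP")
  service_totals <- do.call(rbind, lapply(names(run$services), function(nm) {
    vals <- vapply(six, function(sv) tot(run$services[[nm]], sv), numeric(1))
    data.frame(map = nm, service = six, value = as.numeric(vals))
  }))
  basev <- service_totals[service_totals$map == "baseline", ]
  mb <- match(service_totals$service, basev$service)
  service_totals$pct_change <- 100 *
    (service_totals$value - basev$value[mb]) / abs(basev$value[mb])

  ses_means <- data.frame(
    map = names(run$ses),
    ses_mean = vapply(run$ses, function(s) s$mean, numeric(1))
  )
  list(
    areas = areas,
    service_totals = service_totals,
    ses_means = ses_means,
    correlations = lapply(run$correlations, function(cc) cc$spearman$r)
  )
}
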