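# End-to-end orchestration: synthesize or load data, derive scenario demand
# (Markov for natural development; the LP optimizer for the ecological and
# balanced scenarios), allocate spatially with the CA, value the results, and
# compute trade-off statistics — under one config with a reproducibility
# manifest.

#' Pipeline configuration
#'
#' @param scenarios subset of `c("nd", "epd", "eed")`.
#' @param landscape a [landscape_config()] (the synthetic input block).
#' @param seed global seed; per-module seeds are derived from it by a stable
#'   string hash, so one knob reproduces the whole run.
#' @param grid_size_m ESV evaluation-grid edge (metres).
#' @param markov_steps Markov projection periods for the ND demand.
#' @param ca overrides for [ca_params()] (list).
#' @param eed_weight ecological weight for the balanced scenario.
#' @param published_tables run the table-only valuation path (no rasters): the
#'   packaged coefficient and area tables reproduce the published totals,
#'   decompositions and scenario changes.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenarios = c("nd", "epd", "eed"),
                            landscape = landscape_config(),
                            seed = 1,
                            grid_size_m = 2000,
                            markov_steps = 2,
                            ca = list(),
                            eed_weight = 0.5,
                            published_tables = FALSE) {
  stopifnot(length(scenarios) >= 1, all(scenarios %in% c("nd", "epd", "eed")))
  structure(list(scenarios = scenarios, landscape = landscape, seed = seed,
                 grid_size_m = grid_size_m, markov_steps = markov_steps,
                 ca = ca, eed_weight = eed_weight,
                 published_tables = published_tables),
            class = "pipeline_config")
}

# Stable per-module seed below 2^31, derived from the global seed and a name.
module_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Short hex digest of an R object (FNV-1a over its serialization), for the
# reproducibility manifest.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the coupled valuation-optimization-allocation pipeline
#'
#' Stage order: quantity prediction (Markov projection for natural
#' development; the constrained LP for the ecological-priority and balanced
#' scenarios, its optimal shares scaled to the landscape's total area) ->
#' spatial allocation (suitability surfaces + patch CA) -> valuation (total
#' and per-category ESV, change against the second observed date) ->
#' trade-off statistics on the evaluation grid. With `published_tables = TRUE`
#' the raster stages are skipped and the packaged published tables are
#' revalued end to end.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list): `manifest`, and per mode either `tables`
#'   (published-table path) or `scenarios` (per-scenario list with `demand`,
#'   `raster`, `esv`, `change`, `tradeoffs`), plus `baseline` and `markov`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(config_hash = config_hash(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("esvland")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (config$published_tables) {
    return(list(manifest = manifest, tables = published_table_results()))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ls_cfg <- config$landscape
  ls_cfg$seed <- module_seed(config$seed, "landscape")
  pair <- stage("synthetic_landscape", generate_lulc_pair(ls_cfg))
  dem <- stage("synthetic_landscape", generate_dem(ls_cfg))
  drivers <- stage("synthetic_landscape",
                   generate_drivers(dem, pair$t1, ls_cfg))
  P <- stage("markov_demand", estimate_transition_matrix(pair$t1, pair$t2))
  total_ha <- sum(pair$areas_t2$area_ha)
  baseline <- stage("esv_valuation", compute_esv(pair$areas_t2))
  samples <- stage("plus_leas", extract_expansion_samples(
    pair$t1, pair$t2, drivers, seed = module_seed(config$seed, "leas")))
  suit <- stage("plus_leas", fit_suitability(
    samples, drivers, seed = module_seed(config$seed, "rf")))
  demands <- list()
  for (sc in config$scenarios) {
    demands[[sc]] <- switch(sc,
      nd = stage("markov_demand",
                 project_areas(pair$areas_t2, P, config$markov_steps)),
      epd = stage("gmop_optimizer", {
        sol <- solve_epd()
        area_table(sol$x / sum(sol$x) * total_ha, label = "epd")
      }),
      eed = stage("gmop_optimizer", {
        sol <- solve_eed(w = config$eed_weight)
        area_table(sol$x / sum(sol$x) * total_ha, label = "eed")
      }))
  }
  results <- list()
  for (sc in config$scenarios) {
    ca <- do.call(ca_params, utils::modifyList(
      list(seed = module_seed(config$seed, paste0("cars_", sc))), config$ca))
    alloc <- stage("plus_cars",
                   run_cars(pair$t2, suit, demands[[sc]], params = ca))
    esv <- stage("esv_valuation",
                 compute_esv(raster_area_table(alloc$raster, sc)))
    grid <- stage("esv_valuation",
                  esv_raster(alloc$raster, grid_size_m = config$grid_size_m))
    stats <- stage("tradeoff_synergy", tradeoff_statistics(grid))
    results[[sc]] <- list(demand = demands[[sc]], raster = alloc$raster,
                          converged = alloc$converged, esv = esv,
                          change = esv_change(baseline, esv),
                          grid = grid, tradeoffs = stats)
  }
  list(manifest = manifest, markov = P, baseline = baseline,
       scenarios = results)
}

# Table-only valuation path over the packaged published tables.
published_table_results <- function() {
  tabs <- basin_areas()
  coeffs <- esv_coefficients()
  res <- lapply(tabs, compute_esv, coeffs = coeffs)
  totals <- vapply(res, function(r) format_esv(r$total), numeric(1))
  svc <- sapply(res, function(r) format_esv(r$by_service))
  rownames(svc) <- rownames(coeffs)
  changes <- data.frame(
    comparison = c("2020->nd", "2020->epd", "2020->eed", "1990->2000"),
    percent = c(esv_change(res[["2020"]], res[["nd"]])$percent,
                esv_change(res[["2020"]], res[["epd"]])$percent,
                esv_change(res[["2020"]], res[["eed"]])$percent,
                esv_change(res[["1990"]], res[["2000"]])$percent))
  cs <- sensitivity_cs(tabs[["2020"]], coeffs)
  list(totals_1e8 = totals, by_service_1e8 = svc, changes = changes,
       sensitivity = cs, esv = res)
}

#' Format result tables to the reporting conventions
#'
#' Areas in km^2 at two decimals; ESV in 10^8 CNY at two decimals.
#'
#' @param results a [run_pipeline()] bundle.
#' @return list of data.frames: `areas_km2`, `esv_1e8`.
#' @export
report_tables <- function(results) {
  if (!is.null(results$tables)) {
    esv <- data.frame(label = names(results$tables$totals_1e8),
                      total_1e8 = as.numeric(results$tables$totals_1e8))
    return(list(areas_km2 = NULL, esv_1e8 = esv))
  }
  areas <- do.call(rbind, lapply(names(results$scenarios), function(sc) {
    a <- results$scenarios[[sc]]$demand
    data.frame(scenario = sc, class = a$class_name,
               area_km2 = round(a$area_ha / 100, 2))
  }))
  esv <- do.call(rbind, lapply(names(results$scenarios), function(sc) {
    r <- results$scenarios[[sc]]
    data.frame(scenario = sc, total_1e8 = format_esv(r$esv$total),
               change_pct = r$change$percent)
  }))
  list(areas_km2 = areas, esv_1e8 = esv)
}

#' Round-trip area formatting used by the report tables
#'
#' @param area_ha areas in hectares.
#' @return km^2 at two decimals.
#' @export
format_area_km2 <- function(area_ha) round(area_ha / 100, 2)
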