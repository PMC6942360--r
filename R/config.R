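# cli_reporting: run configuration, validation, orchestration and manifest.
#
# A run configuration is a nested list mirroring a YAML file:
#
#   seed: 1
#   output_dir: results
#   verbosity: info            # quiet | info | debug
#   figures: true
#   landscape:
#     side_m: 3163
#     mean_area_ha: 0.5
#     sd_area_ha: 0.2
#     min_dist_m: 10
#     initial_age_mode: uniform0_100   # or zero
#   grid:
#     species: all             # "all", a vector of ids, or a species CSV path
#     covers: [0.05, 0.10, 0.20]
#     dynamisms: [0.0, 0.05, 0.10, 0.20]
#     iterations: 500
#     steps: 100
#     init_occupancy: 0.5
#     fresh_landscape_per_iteration: true
#     extinction_rule: product # product | or
#
# Unknown keys are rejected (typos must not silently fall back to
# defaults) and every reported problem names the offending key.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "spomdyn-results",
    verbosity = "info",
    figures = FALSE,
    landscape = list(side_m = 3163, mean_area_ha = 0.5, sd_area_ha = 0.2,
                     min_dist_m = 10, initial_age_mode = "uniform0_100"),
    grid = list(species = "all", covers = c(0.05, 0.10, 0.20),
                dynamisms = c(0, 0.05, 0.10, 0.20), iterations = 500L,
                steps = 100L, init_occupancy = 0.5,
                fresh_landscape_per_iteration = TRUE, extinction_rule = "product")
  )
}

config_fail <- function(key, msg) {
  stop("invalid config: key '", key, "' ", msg, call. = FALSE)
}

#' Validate a run configuration
#'
#' Checks key names (unknown keys are an error) and value ranges; every
#' diagnostic names the offending key. Missing keys take documented
#' defaults.
#'
#' @param config a nested list as read from a YAML config file.
#' @return the completed configuration (defaults filled in), class
#'   `run_config`.
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  check_keys <- function(x, allowed, prefix) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      config_fail(paste0(prefix, unknown[1]), "is not a recognised key")
    }
  }
  check_keys(config, names(defaults), "")
  check_keys(config$landscape, names(defaults$landscape), "landscape.")
  check_keys(config$grid, names(defaults$grid), "grid.")
  cfg <- modifyList(defaults, config)

  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    config_fail("seed", "must be a single integer")
  }
  if (!cfg$verbosity %in% c("quiet", "info", "debug")) {
    config_fail("verbosity", "must be quiet, info or debug")
  }
  if (!is.logical(cfg$figures)) config_fail("figures", "must be true/false")
  L <- cfg$landscape
  if (L$side_m <= 0) config_fail("landscape.side_m", "must be positive")
  if (L$mean_area_ha <= 0) config_fail("landscape.mean_area_ha",
                                       "must be positive")
  if (L$sd_area_ha < 0) config_fail("landscape.sd_area_ha",
                                    "must be non-negative")
  if (L$min_dist_m < 0) config_fail("landscape.min_dist_m",
                                    "must be non-negative")
  if (!L$initial_age_mode %in% c("uniform0_100", "zero")) {
    config_fail("landscape.initial_age_mode",
                "must be uniform0_100 or zero")
  }
  G <- cfg$grid
  if (any(G$covers <= 0 | G$covers >= 1)) {
    config_fail("grid.covers", "values must lie strictly between 0 and 1")
  }
  if (any(G$dynamisms < 0 | G$dynamisms > 1)) {
    config_fail("grid.dynamisms", "values must lie in [0, 1]")
  }
  if (G$iterations < 1) config_fail("grid.iterations", "must be >= 1")
  if (G$steps < 1) config_fail("grid.steps", "must be >= 1")
  if (G$init_occupancy < 0 || G$init_occupancy > 1) {
    config_fail("grid.init_occupancy", "must lie in [0, 1]")
  }
  if (!G$extinction_rule %in% c("or", "product")) {
    config_fail("grid.extinction_rule", "must be or or product")
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration file
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly. A config round-trips
#'   through the file losslessly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a `run_config` (or plain nested list).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_species <- function(spec) {
  all_species <- build_virtual_species_set()
  if (identical(spec, "all")) {
    return(all_species)
  }
  if (is.character(spec) && length(spec) == 1 && file.exists(spec)) {
    return(read_species_set(spec))
  }
  ids <- as.integer(spec)
  if (!all(ids %in% all_species$species_id)) {
    config_fail("grid.species", "contains unknown species ids")
  }
  all_species[all_species$species_id %in% ids, , drop = FALSE]
}

#' Build a [scenario_grid()] from a run configuration
#'
#' @param config a validated `run_config`.
#' @return a `scenario_grid`.
#' @export
config_to_grid <- function(config) {
  config <- validate_run_config(unclass(config))
  L <- config$landscape
  G <- config$grid
  scenario_grid(
    species = config_species(G$species),
    covers = G$covers, dynamisms = G$dynamisms,
    iterations = G$iterations, steps = G$steps,
    init_occupancy = G$init_occupancy, base_seed = config$seed,
    side = L$side_m, mean_area = L$mean_area_ha, sd_area = L$sd_area_ha,
    min_dist = L$min_dist_m, initial_age_mode = L$initial_age_mode,
    fresh_landscape_per_iteration = G$fresh_landscape_per_iteration,
    extinction_rule = G$extinction_rule
  )
}

# Polynomial rolling hash over a string; used only to fingerprint configs
# in the run manifest.
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Execute a configured experiment, writing all outputs to disk
#'
#' Runs [run_experiment()] for the configured grid and writes to
#' `output_dir`:
#' * `results.csv` — one row per scenario cell,
#' * `iterations.csv` — one row per (cell, iteration),
#' * `seeds.csv` — the per-cell seed log from [enumerate_scenarios()],
#' * `manifest.json` — config (with fingerprint), package version, R
#'   version and timestamps,
#' * `config.yaml` — the completed configuration actually used,
#' * with `figures: true`, `occupancy.pdf` and its sidecar
#'   `occupancy_data.csv` (see [save_occupancy_figure()]).
#'
#' @param config a `run_config`, or the path of a YAML config file.
#' @param workers forked workers for [run_experiment()].
#' @return the results data frame, invisibly.
#' @export
run_from_config <- function(config, workers = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  grid <- config_to_grid(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  started <- Sys.time()
  results <- run_experiment(grid, workers = workers, keep_iterations = TRUE,
                            progress = config$verbosity != "quiet")
  finished <- Sys.time()

  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(results, out("results.csv"), row.names = FALSE)
  utils::write.csv(attr(results, "iterations"), out("iterations.csv"),
                   row.names = FALSE)
  utils::write.csv(enumerate_scenarios(grid), out("seeds.csv"),
                   row.names = FALSE)
  write_run_config(config, out("config.yaml"))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = unclass(config),
    config_fingerprint = config_hash(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("spomdyn")),
    r_version = R.version.string,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    n_cells = nrow(results),
    n_failed = if (is.null(attr(results, "failures"))) 0L
               else nrow(attr(results, "failures"))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (isTRUE(config$figures)) {
    save_occupancy_figure(results, out("occupancy.pdf"))
  }
  invisible(results)
}
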