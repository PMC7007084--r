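default_config <- function() {
  list(
    inputs = list(nodes = "nodes.csv", edges = "edges.csv",
                  demand = "demand.csv", facilities = "facilities.csv",
                  scenarios = NULL),
    scheme = list(catchment_minutes = 30, breakpoints = c(10, 20, 30),
                  weights = c(1, 0.42, 0.03), beta = 1.15),
    speeds_kmh = as.list(default_class_speeds),
    bands_minutes = c(10, 20, 30),
    max_snap_m = 5000,
    output_dir = "results",
    scenario_names = NULL,
    flags = list(weighted_means = FALSE, exclude_unreachable = TRUE),
    seed = NULL
  )
}

#' Read a pipeline run configuration
#'
#' Reads a declarative YAML configuration and fills unset keys with the
#' package defaults (30-minute catchment, 1/0.42/0.03 weights, 10/20/30
#' bands, class speed table). Relative input paths are resolved against the
#' config file's directory.
#'
#' @param path YAML config path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_catchfca(sprintf("config file not found: %s", path), "io_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  base <- dirname(normalizePath(path))
  cfg$inputs <- lapply(cfg$inputs, function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  })
  if (!grepl("^(/|[A-Za-z]:)", cfg$output_dir)) {
    cfg$output_dir <- file.path(base, cfg$output_dir)
  }
  structure(cfg, class = "run_config")
}

config_scheme <- function(cfg) {
  decay_scheme(
    catchment = cfg$scheme$catchment_minutes,
    breakpoints = unlist(cfg$scheme$breakpoints),
    weights = unlist(cfg$scheme$weights),
    beta = cfg$scheme$beta
  )
}

#' Load and validate every input referenced by a configuration
#'
#' Fails with an informative error naming the offending file or record;
#' on success returns the loaded, validated objects.
#'
#' @param config A `run_config` (or a YAML path).
#' @return List: `network`, `demand`, `facilities`, `scenarios` (named list
#'   of facility-id vectors, or `NULL`), `scheme`, `config`.
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("nodes", "edges", "demand", "facilities")) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop_catchfca(sprintf("input '%s' missing or not found: %s",
                            key, if (is.null(p)) "<unset>" else p), "io_error")
    }
  }
  network <- load_road_network(config$inputs$nodes, config$inputs$edges)
  demand <- load_points(config$inputs$demand, "demand")
  facilities <- load_points(config$inputs$facilities, "facility")
  scenarios <- NULL
  if (!is.null(config$inputs$scenarios)) {
    if (!file.exists(config$inputs$scenarios)) {
      stop_catchfca(sprintf("scenarios file not found: %s", config$inputs$scenarios),
                    "io_error")
    }
    scen_tab <- readr::read_csv(config$inputs$scenarios, show_col_types = FALSE,
                                progress = FALSE)
    require_columns(scen_tab, c("scenario", "facility_id"), "scenarios table")
    unknown <- setdiff(scen_tab$facility_id, facilities$id)
    if (length(unknown) > 0) {
      stop_catchfca(sprintf("scenario references unknown facility id(s): %s",
                            paste(unknown, collapse = ", ")), "contract_error")
    }
    scenarios <- split(as.character(scen_tab$facility_id), scen_tab$scenario)
    if (!is.null(config$scenario_names)) {
      missing <- setdiff(config$scenario_names, names(scenarios))
      if (length(missing) > 0) {
        stop_catchfca(sprintf("scenario(s) not defined: %s",
                              paste(missing, collapse = ", ")), "contract_error")
      }
      scenarios <- scenarios[config$scenario_names]
    }
  }
  list(network = network, demand = demand, facilities = facilities,
       scenarios = scenarios, scheme = config_scheme(config), config = config)
}

activate_scenario <- function(facilities, facility_ids) {
  facilities$active <- facilities$id %in% facility_ids
  facilities
}

compute_scenario <- function(inputs, facility_ids, demand_nodes, facility_nodes,
                             name = "scenario") {
  fac <- activate_scenario(inputs$facilities, facility_ids)
  act_nodes <- facility_nodes[facility_nodes$id %in% facility_ids &
                                !is.na(facility_nodes$node_id), , drop = FALSE]
  ttm <- od_matrix(inputs$network, demand_nodes, act_nodes,
                   cutoff = inputs$scheme$catchment)
  nearest <- nearest_facility_time(inputs$network, demand_nodes, act_nodes)
  surface <- accessibility_surface(ttm, inputs$demand, fac,
                                   scheme = inputs$scheme, nearest = nearest)
  coverage <- coverage_table(nearest, inputs$demand,
                             bands = unlist(inputs$config$bands_minutes))
  meanmin <- mean_nearest_time(
    nearest, inputs$demand,
    exclude_unreachable = isTRUE(inputs$config$flags$exclude_unreachable)
  )
  regional <- regional_summary(surface,
                               weighted = isTRUE(inputs$config$flags$weighted_means))
  list(name = name, facilities = fac, ttm = ttm, nearest = nearest,
       surface = surface, coverage = coverage, mean_minutes = meanmin,
       regional = regional,
       result = scenario_result(coverage, meanmin, regional))
}

write_surface_csv <- function(surface, path) {
  out <- tibble::tibble(
    demand_id = surface$demand_id,
    region = surface$region,
    population = surface$population,
    raw_index = surface$raw,
    std_index = surface$std,
    nearest_minutes = if ("nearest_minutes" %in% names(surface)) {
      surface$nearest_minutes
    } else NA_real_
  )
  readr::write_csv(out, path, progress = FALSE)
}

conservation_check <- function(scen, demand) {
  ft <- attr(scen$surface, "facility_table")
  supplied <- sum(ft$supply[ft$denom > 0])
  delivered <- sum(demand$population * scen$surface$raw)
  list(supplied = supplied, delivered = delivered,
       rel_err = if (supplied > 0) abs(delivered - supplied) / supplied else 0)
}

#' Run the full accessibility pipeline
#'
#' Loads and validates the configured inputs, snaps demand and facilities
#' onto the network, computes the travel-time matrix, the E2SFCA surface,
#' the coverage table and regional summaries for every configured scenario
#' (or a single all-facilities scenario when none are configured), writes
#' every result table plus a structured log to the output directory, and
#' — when at least two scenarios are configured — the comparison between
#' the first two.
#'
#' Outputs: `travel_times_<scenario>.csv`, `accessibility_<scenario>.csv`
#' (`demand_id,region,population,raw_index,std_index,nearest_minutes`),
#' `coverage_<scenario>.csv`, `regional_<scenario>.csv`,
#' `comparison_<a>_vs_<b>.csv` / `.txt`, `run_log.txt` and
#' `config_resolved.yaml` (full provenance of defaults).
#'
#' @param config A `run_config` or a YAML config path.
#' @return Invisibly, a named list of per-scenario result lists plus
#'   `comparison` (or `NULL`).
#' @export
run_accessibility <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  inputs <- withCallingHandlers(
    validate_inputs(config),
    warning = function(w) {
      note("WARNING [load]: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  snap <- function(points, what) {
    withCallingHandlers(
      snap_to_network(points, inputs$network, max_snap = config$max_snap_m),
      warning = function(w) {
        note("WARNING [snap %s]: %s", what, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  demand_nodes <- snap(inputs$demand, "demand")
  facility_nodes <- snap(inputs$facilities, "facilities")
  note("snapped %d/%d demand points, %d/%d facilities",
       sum(demand_nodes$snapped), nrow(demand_nodes),
       sum(facility_nodes$snapped), nrow(facility_nodes))

  scenarios <- inputs$scenarios
  if (is.null(scenarios)) scenarios <- list(all = inputs$facilities$id)
  scen_names <- if (is.list(scenarios) && !is.null(names(scenarios))) {
    names(scenarios)
  } else {
    vapply(scenarios, `[[`, character(1), "name")
  }

  results <- list()
  for (i in seq_along(scenarios)) {
    nm <- scen_names[i]
    ids <- scenarios[[i]]
    if (is.list(ids)) ids <- ids$facility_ids
    scen <- withCallingHandlers(
      compute_scenario(inputs, ids, demand_nodes, facility_nodes, name = nm),
      warning = function(w) {
        note("WARNING [%s]: %s", nm, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    cons <- conservation_check(scen, inputs$demand)
    note("scenario %s: %d active facilities; supply delivered %.6f of %.6f (rel err %.3g)",
         nm, length(ids), cons$delivered, cons$supplied, cons$rel_err)
    write_od_matrix(scen$ttm,
                    file.path(config$output_dir, sprintf("travel_times_%s.csv", nm)))
    write_surface_csv(scen$surface,
                      file.path(config$output_dir, sprintf("accessibility_%s.csv", nm)))
    write_coverage_table(scen$coverage,
                         file.path(config$output_dir, sprintf("coverage_%s.csv", nm)))
    write_regional_summary(scen$regional,
                           file.path(config$output_dir, sprintf("regional_%s.csv", nm)))
    results[[nm]] <- scen
  }

  comparison <- NULL
  if (length(results) >= 2) {
    a <- scen_names[1]; b <- scen_names[2]
    comparison <- compare_scenarios(results[[a]]$result, results[[b]]$result)
    write_comparison(
      comparison,
      file.path(config$output_dir, sprintf("comparison_%s_vs_%s.csv", a, b)),
      file.path(config$output_dir, sprintf("comparison_%s_vs_%s.txt", a, b))
    )
    note("comparison %s -> %s: beyond-catchment delta %+g people (%+.1f p.p.), mean time delta %+.2f min",
         a, b,
         comparison$bands$count_delta[nrow(comparison$bands)],
         comparison$bands$share_delta_pp[nrow(comparison$bands)],
         comparison$mean_minutes$delta)
  }

  yaml::write_yaml(unclass(config), file.path(config$output_dir, "config_resolved.yaml"))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(c(results, list(comparison = comparison)))
}

#' Compare two named scenarios from a configuration
#'
#' Recomputes the accessibility surfaces for the two named scenarios and
#' writes the comparison CSV and text summary to the output directory.
#'
#' @param config A `run_config` or YAML path.
#' @param scenario_a,scenario_b Scenario names defined in the config's
#'   scenarios table.
#' @return The `scenario_comparison`, invisibly.
#' @export
run_compare <- function(config, scenario_a, scenario_b) {
  if (is.character(config)) config <- read_run_config(config)
  inputs <- suppressWarnings(validate_inputs(config))
  if (is.null(inputs$scenarios)) {
    stop_catchfca("no scenarios table configured", "contract_error")
  }
  for (s in c(scenario_a, scenario_b)) {
    if (!s %in% names(inputs$scenarios)) {
      stop_catchfca(sprintf("unknown scenario name: %s", s), "contract_error")
    }
  }
  demand_nodes <- suppressWarnings(
    snap_to_network(inputs$demand, inputs$network, max_snap = config$max_snap_m))
  facility_nodes <- suppressWarnings(
    snap_to_network(inputs$facilities, inputs$network, max_snap = config$max_snap_m))
  sa <- suppressWarnings(compute_scenario(inputs, inputs$scenarios[[scenario_a]],
                                          demand_nodes, facility_nodes, scenario_a))
  sb <- suppressWarnings(compute_scenario(inputs, inputs$scenarios[[scenario_b]],
                                          demand_nodes, facility_nodes, scenario_b))
  comparison <- compare_scenarios(sa$result, sb$result)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_comparison(
    comparison,
    file.path(config$output_dir,
              sprintf("comparison_%s_vs_%s.csv", scenario_a, scenario_b)),
    file.path(config$output_dir,
              sprintf("comparison_%s_vs_%s.txt", scenario_a, scenario_b))
  )
  invisible(comparison)
}
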