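#' Specification of a synthetic study region
#'
#' Bundles every parameter of the seeded synthetic-region generator: a grid
#' road network with diagonal shortcuts and pruned edges, a population
#' surface mixing dense urban cores with a sparse uniform periphery,
#' facilities placed preferentially at high-population nodes, and a reform
#' scenario that closes the facilities with the smallest weighted catchment
#' populations (emulating rural closures).
#'
#' The defaults emulate the mainland-Portugal study setting: ten million
#' inhabitants, 70% of them around five urban cores, 73 emergency
#' facilities before the reform and 15 closures, on a 280 km grid with
#' 5 km node spacing.
#'
#' @param seed Integer seed; every generator draw derives from it.
#' @param extent_km Side of the square region, km.
#' @param spacing_km Grid node spacing, km.
#' @param edge_perturbation Fraction of grid edges removed (connectivity is
#'   preserved via a retained spanning tree), creating periphery detours.
#' @param diagonal_fraction Fraction of grid cells that get a diagonal
#'   shortcut.
#' @param n_urban_cores Number of urban cores; 0 gives a uniform population.
#' @param urban_share Share of the population attached to the cores, in
#'   `[0, 1]`.
#' @param urban_sigma_km Gaussian kernel bandwidth of the cores, km.
#' @param total_population Region population (integer; exactly honoured via
#'   largest-remainder rounding).
#' @param n_facilities Facilities in the before-reform scenario.
#' @param n_closures Facilities removed by the reform; must be smaller than
#'   `n_facilities`.
#' @param gamma Facility-placement preference exponent: placement
#'   probability is proportional to `population^gamma`.
#' @param physicians Named vector of physician counts per service level
#'   (`BES` basic, `MSES` medical-surgical, `MES` multipurpose).
#' @param level_shares Named shares of facilities per level (highest-demand
#'   sites get the highest level).
#' @param n_regions Number of region labels (spatial partition).
#' @return A validated list of class `region_spec`.
#' @export
region_spec <- function(seed = 1L,
                        extent_km = 280,
                        spacing_km = 5,
                        edge_perturbation = 0.15,
                        diagonal_fraction = 0.10,
                        n_urban_cores = 5,
                        urban_share = 0.70,
                        urban_sigma_km = 10,
                        total_population = 10000000,
                        n_facilities = 73,
                        n_closures = 15,
                        gamma = 1.2,
                        physicians = c(BES = 10, MSES = 150, MES = 500),
                        level_shares = c(BES = 0.55, MSES = 0.30, MES = 0.15),
                        n_regions = 5) {
  spec <- list(
    seed = as.integer(seed), extent_km = extent_km, spacing_km = spacing_km,
    edge_perturbation = edge_perturbation, diagonal_fraction = diagonal_fraction,
    n_urban_cores = n_urban_cores, urban_share = urban_share,
    urban_sigma_km = urban_sigma_km, total_population = total_population,
    n_facilities = n_facilities, n_closures = n_closures, gamma = gamma,
    physicians = physicians, level_shares = level_shares, n_regions = n_regions
  )
  stopifnot(
    spec$extent_km > 0, spec$spacing_km > 0, spec$extent_km >= spec$spacing_km,
    spec$edge_perturbation >= 0, spec$edge_perturbation < 1,
    spec$diagonal_fraction >= 0, spec$diagonal_fraction <= 1,
    spec$urban_share >= 0, spec$urban_share <= 1,
    spec$total_population >= 0, spec$n_urban_cores >= 0,
    spec$n_facilities >= 1, spec$n_regions >= 1,
    all(c("BES", "MSES", "MES") %in% names(spec$physicians))
  )
  if (spec$n_closures >= spec$n_facilities) {
    stop_catchfca("n_closures must be smaller than n_facilities", "spec_error")
  }
  structure(spec, class = "region_spec")
}

grid_side <- function(spec) floor(spec$extent_km / spec$spacing_km) + 1L

#' Generate the synthetic grid road network
#'
#' Builds a `side x side` grid of junctions with 4-neighbour segments, adds
#' diagonal shortcuts to a fraction of cells, removes a fraction of edges
#' at random while retaining a spanning tree (so the network stays
#' connected and the periphery acquires detours), and assigns road classes
#' by edge-betweenness rank: the most central 5% of segments become
#' motorways (110 km/h), the next 15% primary (80), the next 30% secondary
#' (60), the rest local roads (40). Deterministic under `spec$seed`.
#'
#' @param spec A [region_spec()].
#' @return A `road_network`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  set.seed(spec$seed + 1L)
  side <- grid_side(spec)
  sp_m <- spec$spacing_km * 1000
  idx <- function(r, c) (r - 1L) * side + c
  n_nodes <- side * side
  node_id <- sprintf("N%05d", seq_len(n_nodes))
  col <- ((seq_len(n_nodes) - 1L) %% side) + 1L
  row <- ((seq_len(n_nodes) - 1L) %/% side) + 1L
  nodes <- tibble::tibble(node_id = node_id,
                          x = (col - 1L) * sp_m, y = (row - 1L) * sp_m)

  # 4-neighbour grid segments
  right <- cbind(idx(row, col), idx(row, col + 1L))[col < side, , drop = FALSE]
  up <- cbind(idx(row, col), idx(row + 1L, col))[row < side, , drop = FALSE]
  ef <- rbind(right, up)
  lengths <- rep(sp_m, nrow(ef))

  # diagonal shortcuts in a fraction of cells
  if (spec$diagonal_fraction > 0 && side > 1L) {
    cells <- expand.grid(r = seq_len(side - 1L), c = seq_len(side - 1L))
    n_diag <- round(spec$diagonal_fraction * nrow(cells))
    if (n_diag > 0) {
      pick <- cells[sort(sample.int(nrow(cells), n_diag)), , drop = FALSE]
      ne <- stats::runif(nrow(pick)) < 0.5   # orientation of the shortcut
      dfrom <- ifelse(ne, idx(pick$r, pick$c), idx(pick$r, pick$c + 1L))
      dto <- ifelse(ne, idx(pick$r + 1L, pick$c + 1L), idx(pick$r + 1L, pick$c))
      ef <- rbind(ef, cbind(dfrom, dto))
      lengths <- c(lengths, rep(sp_m * sqrt(2), nrow(pick)))
    }
  }

  # prune edges, keeping a (random) spanning tree for connectivity
  keep <- rep(TRUE, nrow(ef))
  if (spec$edge_perturbation > 0) {
    g0 <- igraph::graph_from_edgelist(ef, directed = FALSE)
    igraph::E(g0)$eid <- seq_len(nrow(ef))
    tree <- igraph::mst(g0, weights = stats::runif(nrow(ef)))
    protected <- igraph::E(tree)$eid
    removable <- setdiff(seq_len(nrow(ef)), protected)
    n_drop <- min(length(removable), round(spec$edge_perturbation * nrow(ef)))
    if (n_drop > 0) keep[sample(removable, n_drop)] <- FALSE
  }
  ef <- ef[keep, , drop = FALSE]
  lengths <- lengths[keep]

  # road classes by betweenness rank of the retained segments
  g1 <- igraph::graph_from_edgelist(ef, directed = FALSE)
  eb <- igraph::edge_betweenness(g1, weights = lengths)
  rnk <- rank(-eb, ties.method = "first")
  q <- rnk / length(rnk)
  class <- ifelse(q <= 0.05, "motorway",
           ifelse(q <= 0.20, "primary",
           ifelse(q <= 0.50, "secondary", "local")))

  edges <- tibble::tibble(
    from = node_id[ef[, 1]], to = node_id[ef[, 2]],
    length_m = lengths,
    speed_kmh = unname(default_class_speeds[class]),
    road_class = class,
    oneway = FALSE
  )
  load_road_network(nodes, edges)
}

#' Generate the synthetic population surface
#'
#' Places one demand point at every network node. The urban share of the
#' population is distributed proportionally to a sum of Gaussian kernels
#' centred on randomly chosen core nodes; the remainder is spread
#' uniformly. Counts are integers summing exactly to
#' `spec$total_population` (largest-remainder rounding). Region labels
#' partition the nodes by nearest region seed. Deterministic under
#' `spec$seed`.
#'
#' @param spec A [region_spec()].
#' @param network The [generate_network()] output.
#' @return A `demand_points` tibble (id, x, y, population, region) with the
#'   core node ids in attribute `core_nodes`.
#' @export
generate_population <- function(spec, network) {
  stopifnot(inherits(spec, "region_spec"), inherits(network, "road_network"))
  set.seed(spec$seed + 2L)
  nodes <- network$nodes
  n <- nrow(nodes)
  w <- rep(1 / n, n)
  cores <- character(0)
  if (spec$n_urban_cores > 0 && spec$urban_share > 0) {
    core_idx <- sample.int(n, spec$n_urban_cores)
    cores <- nodes$node_id[core_idx]
    sig <- spec$urban_sigma_km * 1000
    kern <- rowSums(vapply(core_idx, function(ci) {
      d2 <- (nodes$x - nodes$x[ci])^2 + (nodes$y - nodes$y[ci])^2
      exp(-d2 / (2 * sig^2))
    }, numeric(n)))
    w <- spec$urban_share * kern / sum(kern) + (1 - spec$urban_share) / n
  }
  pop <- largest_remainder_round(w * spec$total_population,
                                 total = spec$total_population)

  region_seeds <- sample.int(n, spec$n_regions)
  nearest_seed <- vapply(seq_len(n), function(i) {
    which.min(euclid_dist(nodes$x[i], nodes$y[i],
                          nodes$x[region_seeds], nodes$y[region_seeds]))
  }, integer(1))

  demand <- tibble::tibble(
    id = sub("^N", "D", nodes$node_id),
    x = nodes$x, y = nodes$y,
    population = as.numeric(pop),
    region = sprintf("R%d", nearest_seed)
  )
  class(demand) <- c("demand_points", class(demand))
  attr(demand, "core_nodes") <- cores
  demand
}

#' Generate facilities and the closure-based reform scenarios
#'
#' Facilities are placed without replacement at populated demand nodes with
#' probability proportional to `population^gamma`, so they concentrate in
#' the urban cores while the periphery keeps a sparse cover. Service levels
#' follow local demand: the highest-population sites become multipurpose
#' (MES), then medical-surgical (MSES), the rest basic (BES), with
#' level-specific physician counts. The reform closes the `n_closures`
#' facilities with the smallest decay-weighted catchment population (the
#' step-1 denominator), emulating rural closures; `strategy = "random"`
#' closes a uniform random subset instead, for null comparisons.
#' Deterministic under `spec$seed`.
#'
#' @param spec A [region_spec()].
#' @param demand The [generate_population()] output.
#' @param network The [generate_network()] output (needed to evaluate the
#'   catchment populations driving the closure rule).
#' @param scheme A [decay_scheme()] for the closure rule.
#' @param strategy `"lowest_catchment"` (default) or `"random"`.
#' @return List with `facilities` (a `facilities` tibble), and scenarios
#'   `before` / `after` (lists with `name` and `facility_ids`).
#' @export
generate_facilities_and_reform <- function(spec, demand, network,
                                           scheme = decay_scheme(),
                                           strategy = c("lowest_catchment", "random")) {
  stopifnot(inherits(spec, "region_spec"), inherits(network, "road_network"))
  strategy <- match.arg(strategy)
  set.seed(spec$seed + 3L)
  cand <- demand[demand$population > 0, , drop = FALSE]
  if (nrow(cand) < spec$n_facilities) {
    stop_catchfca("fewer populated nodes than facilities requested", "spec_error")
  }
  pick <- sample(nrow(cand), spec$n_facilities,
                 prob = cand$population^spec$gamma)
  sites <- cand[pick, , drop = FALSE]

  # levels by local demand rank
  ord <- order(-sites$population, sites$id, method = "radix")
  n <- spec$n_facilities
  n_mes <- max(1L, round(spec$level_shares[["MES"]] * n))
  n_mses <- max(1L, round(spec$level_shares[["MSES"]] * n))
  lvl <- rep("BES", n)
  lvl[ord[seq_len(min(n_mes, n))]] <- "MES"
  if (n_mes < n) {
    lvl[ord[seq(n_mes + 1L, min(n_mes + n_mses, n))]] <- "MSES"
  }
  facilities <- tibble::tibble(
    id = sprintf("H%03d", seq_len(n)),
    x = sites$x, y = sites$y,
    physicians = as.numeric(spec$physicians[lvl]),
    level = lvl,
    active = TRUE
  )
  class(facilities) <- c("facilities", class(facilities))

  closed <- if (spec$n_closures == 0) {
    character(0)
  } else if (strategy == "random") {
    sort(sample(facilities$id, spec$n_closures))
  } else {
    dn <- snap_to_network(demand, network, max_snap = Inf)
    fn <- snap_to_network(facilities, network, max_snap = Inf)
    ttm <- od_matrix(network, dn, fn, cutoff = scheme$catchment)
    wpop <- catchment_population(ttm, demand, facilities, scheme)
    ord_c <- order(wpop, facilities$id, method = "radix")
    sort(facilities$id[ord_c[seq_len(spec$n_closures)]])
  }

  list(
    facilities = facilities,
    before = list(name = "before", facility_ids = facilities$id),
    after = list(name = "after", facility_ids = setdiff(facilities$id, closed)),
    closed = closed
  )
}

#' Decay-weighted catchment population of every facility
#'
#' The step-1 denominator `sum_k P_k W(d_kj)` for each facility, whether or
#' not it is active.
#'
#' @inheritParams e2sfca
#' @return Named numeric vector over `facilities$id`.
#' @export
catchment_population <- function(ttm, demand, facilities, scheme = decay_scheme()) {
  tt <- tibble::as_tibble(ttm)
  tt$w <- time_decay_weight(tt$minutes, scheme)
  tt$pop <- demand$population[match(tt$demand_id, demand$id)]
  agg <- tt |>
    dplyr::group_by(.data$facility_id) |>
    dplyr::summarise(wpop = sum(.data$pop * .data$w), .groups = "drop")
  out <- setNames(rep(0, nrow(facilities)), facilities$id)
  out[agg$facility_id] <- agg$wpop
  out
}

#' Simulate a complete synthetic study region
#'
#' Runs the three generators and returns the full input bundle for the
#' accessibility pipeline.
#'
#' @param spec A [region_spec()].
#' @param scheme A [decay_scheme()] used by the closure rule.
#' @param strategy Closure strategy, see [generate_facilities_and_reform()].
#' @return List of class `region_bundle`: `spec`, `network`, `demand`,
#'   `facilities`, `scenarios` (named list of `before` / `after`), `closed`.
#' @export
simulate_region <- function(spec = region_spec(), scheme = decay_scheme(),
                            strategy = "lowest_catchment") {
  network <- generate_network(spec)
  demand <- generate_population(spec, network)
  fac <- generate_facilities_and_reform(spec, demand, network, scheme, strategy)
  structure(
    list(spec = spec, network = network, demand = demand,
         facilities = fac$facilities,
         scenarios = list(before = fac$before, after = fac$after),
         closed = fac$closed),
    class = "region_bundle"
  )
}

#' Write a simulated region bundle to a directory
#'
#' Writes `nodes.csv`, `edges.csv`, `demand.csv`, `facilities.csv`,
#' `scenarios.csv` (long form `scenario,facility_id`) and a ready-to-run
#' `config.yaml` so the bundle is consumable by [run_accessibility()]
#' unchanged.
#'
#' @param bundle A `region_bundle` from [simulate_region()].
#' @param dir Output directory (created if missing).
#' @param scheme The [decay_scheme()] echoed into the config.
#' @return Invisibly, the config path.
#' @export
write_bundle <- function(bundle, dir, scheme = decay_scheme()) {
  stopifnot(inherits(bundle, "region_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_road_network(bundle$network, file.path(dir, "nodes.csv"),
                     file.path(dir, "edges.csv"))
  readr::write_csv(tibble::as_tibble(bundle$demand), file.path(dir, "demand.csv"),
                   progress = FALSE)
  readr::write_csv(
    dplyr::select(tibble::as_tibble(bundle$facilities), -"active"),
    file.path(dir, "facilities.csv"), progress = FALSE
  )
  scen <- dplyr::bind_rows(lapply(bundle$scenarios, function(s) {
    tibble::tibble(scenario = s$name, facility_id = s$facility_ids)
  }))
  readr::write_csv(scen, file.path(dir, "scenarios.csv"), progress = FALSE)

  config <- list(
    inputs = list(nodes = "nodes.csv", edges = "edges.csv",
                  demand = "demand.csv", facilities = "facilities.csv",
                  scenarios = "scenarios.csv"),
    scheme = list(catchment_minutes = scheme$catchment,
                  breakpoints = scheme$breakpoints,
                  weights = scheme$weights, beta = scheme$beta),
    speeds_kmh = as.list(default_class_speeds),
    bands_minutes = scheme$breakpoints,
    max_snap_m = 2 * bundle$spec$spacing_km * 1000,
    output_dir = "results",
    scenario_names = names(bundle$scenarios),
    flags = list(weighted_means = FALSE, exclude_unreachable = TRUE),
    seed = bundle$spec$seed
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
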