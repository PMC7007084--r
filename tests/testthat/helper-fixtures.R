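# Shared fixtures and independent oracles for the test suite.

# Line network F -- A -- B -- C with travel times 5, 10, 20 min at 60 km/h,
# one facility (10 physicians) at F and demand of 100/200/500 people at
# 5/15/35 minutes: the hand-derived single-facility instance.
toy_region <- function() {
  nodes <- data.frame(node_id = c("F", "A", "B", "C"),
                      x = c(0, 1, 2, 3) * 1000, y = 0)
  edges <- data.frame(from = c("F", "A", "B"), to = c("A", "B", "C"),
                      length_m = c(5, 10, 20) * 1000, speed_kmh = 60,
                      road_class = "local")
  network <- load_road_network(nodes, edges)
  demand <- load_points(
    data.frame(id = c("d1", "d2", "d3"), x = c(1, 2, 3) * 1000, y = 0,
               population = c(100, 200, 500), region = "R1"),
    "demand"
  )
  facilities <- load_points(
    data.frame(id = "H1", x = 0, y = 0, physicians = 10, level = "MES"),
    "facility"
  )
  dn <- snap_to_network(demand, network)
  fn <- snap_to_network(facilities, network)
  list(network = network, demand = demand, facilities = facilities,
       demand_nodes = dn, facility_nodes = fn)
}

# Random connected-ish directed network on n nodes for oracle comparisons.
random_network <- function(n, p = 0.45) {
  ids <- LETTERS[seq_len(n)]
  nodes <- data.frame(node_id = ids, x = seq_len(n) * 100, y = 0)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  edges <- data.frame(
    from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
    length_m = round(runif(sum(keep), 200, 5000)),
    speed_kmh = sample(c(40, 60, 80, 110), sum(keep), replace = TRUE),
    road_class = sample(c("local", "secondary", "primary", "motorway"),
                        sum(keep), replace = TRUE),
    oneway = runif(sum(keep)) < 0.2
  )
  load_road_network(nodes, edges)
}

# Independent shortest-path oracle: exhaustive enumeration of all simple
# directed paths, summing per-arc minutes. Never touches igraph.
brute_force_time <- function(network, origin, destination) {
  arcs <- network$arcs
  best <- Inf
  recurse <- function(at, visited, acc) {
    if (acc >= best) return(invisible(NULL))
    if (at == destination) {
      best <<- acc
      return(invisible(NULL))
    }
    out <- which(arcs$from == at & !(arcs$to %in% visited))
    for (k in out) {
      recurse(arcs$to[k], c(visited, arcs$to[k]), acc + arcs$minutes[k])
    }
  }
  recurse(origin, origin, 0)
  best
}

# Independent E2SFCA oracle: naive double loop over facilities and demand,
# with its own stepped-weight lookup written from the zone definition.
naive_e2sfca <- function(times, pop, supply, catchment = 30,
                         breaks = c(10, 20, 30), w = c(1, 0.42, 0.03)) {
  wt <- function(t) {
    if (!is.finite(t) || t > catchment) return(0)
    if (t <= breaks[1]) return(w[1])          # includes t = 0
    if (t <= breaks[2]) return(w[2])
    w[3]
  }
  nf <- length(supply)
  nd <- length(pop)
  ratio <- numeric(nf)
  for (j in seq_len(nf)) {
    denom <- 0
    for (k in seq_len(nd)) denom <- denom + pop[k] * wt(times[k, j])
    ratio[j] <- if (denom > 0) supply[j] / denom else 0
  }
  acc <- numeric(nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nf)) acc[i] <- acc[i] + ratio[j] * wt(times[i, j])
  }
  list(ratio = ratio, acc = acc)
}

# Random small accessibility instance: full time matrix (with some pairs
# beyond the catchment) plus the travel_time_matrix the package consumes.
random_instance <- function(n_demand, n_fac, cutoff = 30) {
  times <- matrix(runif(n_demand * n_fac, 0, 1.6 * cutoff),
                  nrow = n_demand, ncol = n_fac)
  demand <- tibble::tibble(
    id = sprintf("d%02d", seq_len(n_demand)),
    x = 0, y = 0,
    population = sample(0:5000, n_demand, replace = TRUE),
    region = sample(c("R1", "R2"), n_demand, replace = TRUE)
  )
  class(demand) <- c("demand_points", class(demand))
  facilities <- tibble::tibble(
    id = sprintf("f%02d", seq_len(n_fac)),
    x = 0, y = 0,
    physicians = sample(0:80, n_fac, replace = TRUE),
    level = "BES", active = TRUE
  )
  class(facilities) <- c("facilities", class(facilities))
  long <- expand.grid(i = seq_len(n_demand), j = seq_len(n_fac))
  long$minutes <- times[cbind(long$i, long$j)]
  long <- long[long$minutes <= cutoff, , drop = FALSE]
  ttm <- tibble::tibble(
    demand_id = demand$id[long$i],
    facility_id = facilities$id[long$j],
    minutes = long$minutes
  )
  attr(ttm, "cutoff") <- cutoff
  class(ttm) <- c("travel_time_matrix", class(ttm))
  list(times = times, demand = demand, facilities = facilities, ttm = ttm)
}

# Small, fast region specification used by property tests.
small_spec <- function(seed, ...) {
  args <- modifyList(
    list(seed = seed, extent_km = 60, spacing_km = 6,
         n_urban_cores = 2, total_population = 200000,
         n_facilities = 8, n_closures = 2, n_regions = 3,
         urban_sigma_km = 8),
    list(...)
  )
  do.call(region_spec, args)
}
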