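#' Travel time of a road segment
#'
#' Minutes to traverse `length` metres at `speed` km/h:
#' `(length / 1000) / speed * 60`.
#'
#' @param length Segment length in metres, > 0 (vectorised).
#' @param speed Travel speed in km/h, > 0 (vectorised).
#' @return Minutes.
#' @examples
#' edge_travel_time(1000, 60)  # 1 minute
#' @export
edge_travel_time <- function(length, speed) {
  if (any(length <= 0) || any(speed <= 0)) {
    stop_catchfca("length and speed must be positive", "validation_error")
  }
  (length / 1000) / speed * 60
}

check_nodes_known <- function(network, ids) {
  unknown <- setdiff(ids, network$nodes$node_id)
  if (length(unknown) > 0) {
    stop_catchfca(
      sprintf("unknown node id(s): %s", paste(unknown, collapse = ", ")),
      "unknown_node"
    )
  }
}

#' Shortest network travel time between two nodes
#'
#' Exact minimum over all directed paths of summed arc travel times
#' (Dijkstra on the arc `minutes` weights). Equal-cost alternatives resolve
#' to the same value, so no tie-break on times is needed.
#'
#' @param network A `road_network`.
#' @param origin,destination Node ids.
#' @return Minutes, or `Inf` if the destination is unreachable.
#' @export
shortest_travel_time <- function(network, origin, destination) {
  stopifnot(inherits(network, "road_network"))
  check_nodes_known(network, c(origin, destination))
  as.numeric(igraph::distances(
    network$graph, v = origin, to = destination,
    mode = "out", weights = igraph::E(network$graph)$minutes,
    algorithm = "dijkstra"
  ))
}

node_time_matrix <- function(network, from_nodes, to_nodes) {
  # one igraph call; rows = unique origins, cols = unique destinations
  igraph::distances(
    network$graph, v = from_nodes, to = to_nodes,
    mode = "out", weights = igraph::E(network$graph)$minutes,
    algorithm = "dijkstra"
  )
}

#' Origin-destination travel-time matrix under a catchment cutoff
#'
#' Computes shortest travel times from every snapped demand point to every
#' snapped, active facility and keeps the pairs within `cutoff` minutes.
#' An absent pair means "beyond cutoff or unreachable". Unsnapped points
#' (`node_id` `NA`) are excluded.
#'
#' @param network A `road_network`.
#' @param demand_nodes Tibble `id`, `node_id` from [snap_to_network()].
#' @param facility_nodes Tibble `id`, `node_id` from [snap_to_network()].
#' @param cutoff Catchment size in minutes (default 30).
#' @return A `travel_time_matrix`: long tibble `demand_id`, `facility_id`,
#'   `minutes` with the cutoff stored as an attribute.
#' @export
od_matrix <- function(network, demand_nodes, facility_nodes, cutoff = 30) {
  stopifnot(inherits(network, "road_network"))
  d <- demand_nodes[!is.na(demand_nodes$node_id), , drop = FALSE]
  f <- facility_nodes[!is.na(facility_nodes$node_id), , drop = FALSE]
  if (nrow(d) == 0 || nrow(f) == 0) {
    stop_catchfca("od_matrix needs at least one snapped demand point and one facility",
                  "contract_error")
  }
  check_nodes_known(network, c(d$node_id, f$node_id))
  dn <- unique(d$node_id)
  fn <- unique(f$node_id)
  tm <- node_time_matrix(network, dn, fn)
  long <- tibble::tibble(
    demand_id = rep(d$id, times = nrow(f)),
    facility_id = rep(f$id, each = nrow(d)),
    minutes = as.vector(tm[match(d$node_id, dn), match(f$node_id, fn), drop = FALSE])
  )
  long <- long[is.finite(long$minutes) & long$minutes <= cutoff, , drop = FALSE]
  structure(long, cutoff = cutoff, class = c("travel_time_matrix", class(long)))
}

#' Uncapped nearest-facility travel times
#'
#' For each snapped demand point, the minimum shortest travel time over the
#' active facilities, with no cutoff: average travel times above the
#' catchment size are meaningful for reporting. Demand unreachable from
#' every facility gets `Inf` and is counted in the beyond-catchment band by
#' [coverage_table()].
#'
#' @inheritParams od_matrix
#' @return Tibble `demand_id`, `minutes` (`Inf` = unreachable).
#' @export
nearest_facility_time <- function(network, demand_nodes, facility_nodes) {
  stopifnot(inherits(network, "road_network"))
  d <- demand_nodes[!is.na(demand_nodes$node_id), , drop = FALSE]
  f <- facility_nodes[!is.na(facility_nodes$node_id), , drop = FALSE]
  if (nrow(f) == 0) {
    stop_catchfca("nearest_facility_time needs at least one facility", "contract_error")
  }
  check_nodes_known(network, c(d$node_id, f$node_id))
  dn <- unique(d$node_id)
  fn <- unique(f$node_id)
  tm <- node_time_matrix(network, dn, fn)
  mins <- apply(tm, 1, min)
  tibble::tibble(
    demand_id = d$id,
    minutes = as.numeric(mins[match(d$node_id, dn)])
  )
}

#' Write a travel-time matrix as long-form CSV
#'
#' @param ttm A `travel_time_matrix`.
#' @param path Output path (`demand_id,facility_id,minutes`).
#' @export
write_od_matrix <- function(ttm, path) {
  readr::write_csv(tibble::as_tibble(ttm), path, progress = FALSE)
  invisible(path)
}
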