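#' Road classes understood by the travel-time model
#'
#' Class-specific default speeds (km/h) used when an edge table carries a
#' road class but no speed column. Ambulance travel is modelled at ordinary
#' car speeds per class; congestion is not modelled.
#'
#' @format Named numeric vector, km/h.
#' @export
default_class_speeds <- c(motorway = 110, primary = 80, secondary = 60, local = 40)

road_classes <- names(default_class_speeds)

as_input_table <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop_catchfca(sprintf("%s file not found: %s", what, x), "io_error")
    }
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.data.frame(x)) {
    stop_catchfca(sprintf("%s must be a data frame or a CSV path", what), "type_error")
  }
  tibble::as_tibble(x)
}

require_columns <- function(tab, cols, what) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    stop_catchfca(
      sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")),
      "contract_error"
    )
  }
}

#' Load and validate a road network
#'
#' Reads junction nodes and road segments into a validated directed network.
#' Input segments are undirected by default: each row is expanded into two
#' opposing arcs. One-way streets are supported through an optional logical
#' `oneway` column (`TRUE` keeps only the `from -> to` arc).
#'
#' Coordinates are planar metres in a projected CRS chosen by the caller;
#' travel time is computed from edge lengths, never from coordinates, so no
#' geodesy is performed.
#'
#' @param nodes Data frame or CSV path with columns `node_id`, `x`, `y`
#'   (metres).
#' @param edges Data frame or CSV path with columns `from`, `to`, `length_m`,
#'   `speed_kmh`, `road_class` and optionally `oneway`.
#' @return An object of class `road_network`: a list with `nodes` (tibble),
#'   `edges` (the validated undirected input table), `arcs` (directed
#'   expansion with a `minutes` cost column) and `graph` (an igraph).
#' @examples
#' nodes <- data.frame(node_id = c("A", "B"), x = c(0, 1000), y = 0)
#' edges <- data.frame(from = "A", to = "B", length_m = 1000,
#'                     speed_kmh = 60, road_class = "local")
#' net <- load_road_network(nodes, edges)
#' net$arcs$minutes
#' @export
load_road_network <- function(nodes, edges) {
  nodes <- as_input_table(nodes, "nodes table")
  edges <- as_input_table(edges, "edges table")
  require_columns(nodes, c("node_id", "x", "y"), "nodes table")
  require_columns(edges, c("from", "to", "length_m", "speed_kmh", "road_class"),
                  "edges table")

  nodes <- dplyr::mutate(nodes,
    node_id = as.character(.data$node_id),
    x = as.numeric(.data$x), y = as.numeric(.data$y)
  )
  if (anyDuplicated(nodes$node_id)) {
    stop_catchfca("duplicate node_id in nodes table", "contract_error")
  }

  if (nrow(edges) == 0) {
    warn_catchfca("edge table is empty: network has 0 arcs", "empty_edges")
    edges <- tibble::tibble(
      from = character(), to = character(), length_m = numeric(),
      speed_kmh = numeric(), road_class = character(), oneway = logical()
    )
  }
  if (!"oneway" %in% names(edges)) edges$oneway <- FALSE
  edges <- dplyr::mutate(edges,
    from = as.character(.data$from), to = as.character(.data$to),
    length_m = as.numeric(.data$length_m),
    speed_kmh = as.numeric(.data$speed_kmh),
    road_class = as.character(.data$road_class),
    oneway = as.logical(.data$oneway)
  )

  dangling <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(dangling) > 0) {
    stop_catchfca(
      sprintf("edge endpoint(s) not present in nodes table: %s",
              paste(sort(unique(dangling)), collapse = ", ")),
      "dangling_edge"
    )
  }
  if (any(edges$length_m <= 0) || any(edges$speed_kmh <= 0)) {
    bad <- which(edges$length_m <= 0 | edges$speed_kmh <= 0)
    stop_catchfca(
      sprintf("nonpositive length or speed on edge row(s): %s",
              paste(bad, collapse = ", ")),
      "validation_error"
    )
  }
  if (!all(edges$road_class %in% road_classes)) {
    bad <- setdiff(unique(edges$road_class), road_classes)
    stop_catchfca(
      sprintf("unknown road_class value(s): %s (expected %s)",
              paste(bad, collapse = ", "), paste(road_classes, collapse = ", ")),
      "validation_error"
    )
  }

  back <- edges[!edges$oneway, , drop = FALSE]
  arcs <- dplyr::bind_rows(
    edges,
    dplyr::mutate(back, from = back$to, to = back$from)
  )
  arcs <- dplyr::mutate(
    dplyr::select(arcs, -"oneway"),
    minutes = edge_travel_time(.data$length_m, .data$speed_kmh)
  )

  g <- igraph::graph_from_data_frame(
    d = data.frame(from = arcs$from, to = arcs$to),
    directed = TRUE,
    vertices = data.frame(name = nodes$node_id)
  )
  igraph::E(g)$minutes <- arcs$minutes

  structure(
    list(nodes = nodes, edges = edges, arcs = arcs, graph = g),
    class = "road_network"
  )
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d directed arcs (%d input segments)\n",
              nrow(x$nodes), nrow(x$arcs), nrow(x$edges)))
  invisible(x)
}

#' Write a road network back to node/edge CSV tables
#'
#' Writes the undirected input representation, so that
#' `load_road_network(write_road_network(...))` round-trips exactly.
#'
#' @param network A `road_network`.
#' @param nodes_path,edges_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_road_network <- function(network, nodes_path, edges_path) {
  stopifnot(inherits(network, "road_network"))
  readr::write_csv(network$nodes, nodes_path, progress = FALSE)
  readr::write_csv(network$edges, edges_path, progress = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Load demand points or facilities from a table
#'
#' Demand points are population centroids (typically of census statistical
#' subsections) carrying a population count and a region label used for
#' regional aggregation. Facilities are emergency-service sites carrying a
#' supply proxy (physician count) and a service level: `BES` (basic),
#' `MSES` (medical-surgical) or `MES` (multipurpose).
#'
#' @param table Data frame or CSV path. Demand requires columns
#'   `id,x,y,population,region`; facilities require `id,x,y,physicians,level`.
#' @param role `"demand"` or `"facility"`.
#' @return A tibble of class `demand_points` or `facilities`. Facilities gain
#'   an `active` flag, `TRUE` by default (scenarios toggle it).
#' @export
load_points <- function(table, role = c("demand", "facility")) {
  role <- match.arg(role)
  tab <- as_input_table(table, sprintf("%s table", role))
  cols <- if (role == "demand") {
    c("id", "x", "y", "population", "region")
  } else {
    c("id", "x", "y", "physicians", "level")
  }
  require_columns(tab, cols, sprintf("%s table", role))
  if (nrow(tab) == 0) {
    warn_catchfca(sprintf("%s table has 0 rows", role), "empty_points")
  }
  tab <- dplyr::mutate(tab,
    id = as.character(.data$id),
    x = as.numeric(.data$x), y = as.numeric(.data$y)
  )
  if (anyDuplicated(tab$id)) {
    stop_catchfca(sprintf("duplicate id in %s table", role), "contract_error")
  }
  if (role == "demand") {
    tab$population <- as.numeric(tab$population)
    if (any(tab$population < 0)) {
      stop_catchfca(
        sprintf("negative population for demand id(s): %s",
                paste(tab$id[tab$population < 0], collapse = ", ")),
        "validation_error"
      )
    }
    if (nrow(tab) > 0 && any(!nzchar(as.character(tab$region)) | is.na(tab$region))) {
      stop_catchfca("empty region label in demand table", "validation_error")
    }
    tab$region <- as.character(tab$region)
    class(tab) <- c("demand_points", class(tab))
  } else {
    tab$physicians <- as.numeric(tab$physicians)
    if (any(tab$physicians < 0)) {
      stop_catchfca(
        sprintf("negative physician count for facility id(s): %s",
                paste(tab$id[tab$physicians < 0], collapse = ", ")),
        "validation_error"
      )
    }
    levels_ok <- c("BES", "MSES", "MES")
    if (nrow(tab) > 0 && !all(tab$level %in% levels_ok)) {
      stop_catchfca(
        sprintf("unknown facility level(s): %s (expected %s)",
                paste(setdiff(unique(tab$level), levels_ok), collapse = ", "),
                paste(levels_ok, collapse = ", ")),
        "validation_error"
      )
    }
    if (!"active" %in% names(tab)) tab$active <- TRUE
    tab$active <- as.logical(tab$active)
    class(tab) <- c("facilities", class(tab))
  }
  tab
}

#' Snap located points onto network nodes
#'
#' Maps each point to its nearest network node by planar Euclidean distance.
#' Ties are broken by the smallest `node_id` (lexicographic), so snapping is
#' deterministic. Points whose nearest node lies beyond `max_snap` metres are
#' flagged unsnapped (`node_id = NA`) with a warning; downstream computations
#' exclude them rather than silently dropping them.
#'
#' @param points Tibble with `id`, `x`, `y` columns (demand or facilities).
#' @param network A `road_network`.
#' @param max_snap Maximum snap distance in metres (default 5000).
#' @return Tibble `id`, `node_id`, `snap_m`, `snapped`.
#' @export
snap_to_network <- function(points, network, max_snap = 5000) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0) {
    stop_catchfca("cannot snap to an empty network", "contract_error")
  }
  nodes <- network$nodes
  # resolve ties deterministically: sort candidate nodes by id once
  ord <- order(nodes$node_id, method = "radix")
  nx <- nodes$x[ord]; ny <- nodes$y[ord]; nid <- nodes$node_id[ord]
  res <- lapply(seq_len(nrow(points)), function(i) {
    d <- euclid_dist(points$x[i], points$y[i], nx, ny)
    j <- which.min(d)  # first minimum in id order = smallest node_id
    list(node_id = nid[j], snap_m = d[j])
  })
  out <- tibble::tibble(
    id = points$id,
    node_id = vapply(res, `[[`, character(1), "node_id"),
    snap_m = vapply(res, `[[`, numeric(1), "snap_m")
  )
  out$snapped <- out$snap_m <= max_snap
  if (any(!out$snapped)) {
    warn_catchfca(
      sprintf("%d point(s) farther than %g m from any node left unsnapped: %s",
              sum(!out$snapped), max_snap,
              paste(out$id[!out$snapped], collapse = ", ")),
      "unsnapped_points"
    )
    out$node_id[!out$snapped] <- NA_character_
  }
  out
}
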