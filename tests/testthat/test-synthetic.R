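test_that("an unperturbed grid is complete, connected and Manhattan-metric", {
  spec <- region_spec(seed = 3, extent_km = 10, spacing_km = 1,
                      edge_perturbation = 0, diagonal_fraction = 0,
                      n_urban_cores = 1, total_population = 1000,
                      n_facilities = 2, n_closures = 1, n_regions = 2)
  net <- generate_network(spec)
  expect_equal(nrow(net$nodes), 121)
  expect_true(igraph::is_connected(net$graph, mode = "strong"))
  # full 4-neighbour grid: 2 * side * (side - 1) segments
  expect_equal(nrow(net$edges), 2 * 11 * 10)
  # length-shortest paths equal the closed-form Manhattan distance
  dm <- igraph::distances(net$graph, weights = net$arcs$length_m, mode = "out")
  ids <- net$nodes$node_id
  for (pair in list(c(1, 121), c(1, 11), c(5, 115))) {
    a <- pair[1]; b <- pair[2]
    manhattan <- abs(net$nodes$x[a] - net$nodes$x[b]) +
      abs(net$nodes$y[a] - net$nodes$y[b])
    expect_equal(dm[ids[a], ids[b]], manhattan)
  }
})

test_that("perturbed networks stay connected and classed by centrality", {
  spec <- small_spec(5)
  net <- generate_network(spec)
  expect_true(igraph::is_connected(net$graph, mode = "strong"))
  expect_true(all(net$edges$road_class %in% names(default_class_speeds)))
  expect_true(all(sort(unique(net$edges$road_class)) %in%
                    c("local", "motorway", "primary", "secondary")))
  expect_equal(unname(default_class_speeds[net$edges$road_class]),
               net$edges$speed_kmh)
})

test_that("generation is deterministic under the seed", {
  a <- simulate_region(small_spec(11))
  b <- simulate_region(small_spec(11))
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(tibble::as_tibble(a$demand), tibble::as_tibble(b$demand))
  expect_identical(tibble::as_tibble(a$facilities),
                   tibble::as_tibble(b$facilities))
  expect_identical(a$scenarios, b$scenarios)
  c <- simulate_region(small_spec(12))
  expect_false(identical(tibble::as_tibble(a$demand),
                         tibble::as_tibble(c$demand)))
})

test_that("population honours the total exactly and concentrates at cores", {
  spec <- small_spec(21, total_population = 100000, urban_share = 0.7)
  net <- generate_network(spec)
  dem <- generate_population(spec, net)
  expect_equal(sum(dem$population), 100000)
  expect_true(all(dem$population >= 0))
  expect_true(all(dem$population == round(dem$population)))
  expect_true(all(nzchar(dem$region)))
  # most of the mass sits near the cores
  cores <- attr(dem, "core_nodes")
  core_xy <- net$nodes[net$nodes$node_id %in% cores, ]
  near_core <- vapply(seq_len(nrow(dem)), function(i) {
    any(sqrt((dem$x[i] - core_xy$x)^2 + (dem$y[i] - core_xy$y)^2) <=
          2 * spec$urban_sigma_km * 1000)
  }, logical(1))
  expect_gt(sum(dem$population[near_core]) / sum(dem$population), 0.5)

  # no cores: uniform population (equal up to rounding)
  spec0 <- small_spec(21, n_urban_cores = 0, total_population = 100000)
  dem0 <- generate_population(spec0, net)
  expect_lte(diff(range(dem0$population)), 1)
  expect_equal(sum(dem0$population), 100000)
})

test_that("the reform closes the lowest-catchment facilities", {
  spec <- small_spec(31)
  bundle <- simulate_region(spec)
  expect_equal(length(bundle$scenarios$before$facility_ids), 8)
  expect_equal(length(bundle$scenarios$after$facility_ids), 6)
  expect_equal(length(bundle$closed), 2)

  # recompute the step-1 denominators independently and verify the choice
  dn <- snap_to_network(bundle$demand, bundle$network, max_snap = Inf)
  fn <- snap_to_network(bundle$facilities, bundle$network, max_snap = Inf)
  ttm <- od_matrix(bundle$network, dn, fn, cutoff = 30)
  wpop <- catchment_population(ttm, bundle$demand, bundle$facilities)
  ord <- order(wpop, bundle$facilities$id, method = "radix")
  expect_setequal(bundle$closed, bundle$facilities$id[ord[1:2]])

  # no closures: identical scenarios
  b0 <- simulate_region(small_spec(31, n_closures = 0))
  expect_identical(b0$scenarios$before$facility_ids,
                   b0$scenarios$after$facility_ids)

  expect_error(region_spec(n_facilities = 5, n_closures = 5),
               class = "catchfca_spec_error")
})

test_that("the national-scale reform keeps 58 of 73 facilities", {
  spec <- region_spec(seed = 2, extent_km = 100, spacing_km = 5,
                      total_population = 1000000)
  bundle <- simulate_region(spec)
  expect_equal(nrow(bundle$facilities), 73)
  expect_equal(length(bundle$scenarios$after$facility_ids), 58)
})

test_that("generated bundles satisfy every loader invariant", {
  bundle <- simulate_region(small_spec(41))
  tmp <- withr::local_tempdir()
  write_bundle(bundle, tmp)
  net <- load_road_network(file.path(tmp, "nodes.csv"),
                           file.path(tmp, "edges.csv"))
  dem <- load_points(file.path(tmp, "demand.csv"), "demand")
  fac <- load_points(file.path(tmp, "facilities.csv"), "facility")
  expect_equal(net$edges, bundle$network$edges)
  expect_equal(dem$population, bundle$demand$population)
  expect_equal(fac$physicians, bundle$facilities$physicians)
})

test_that("closing facilities degrades coverage and mean time, never improves them", {
  for (seed in c(51, 52, 53)) {
    bundle <- simulate_region(small_spec(seed))
    dn <- snap_to_network(bundle$demand, bundle$network, max_snap = Inf)
    fn <- snap_to_network(bundle$facilities, bundle$network, max_snap = Inf)
    stats <- lapply(bundle$scenarios, function(s) {
      an <- fn[fn$id %in% s$facility_ids, ]
      near <- nearest_facility_time(bundle$network, dn, an)
      list(
        beyond = coverage_table(near, bundle$demand)$beyond$population,
        mean = suppressWarnings(
          mean_nearest_time(near, bundle$demand, exclude_unreachable = TRUE))
      )
    })
    expect_gte(stats$after$beyond, stats$before$beyond)
    expect_gte(stats$after$mean, stats$before$mean)
  }
})
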