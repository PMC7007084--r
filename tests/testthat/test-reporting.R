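toy_nearest <- function() {
  tibble::tibble(demand_id = c("d1", "d2", "d3"), minutes = c(5, 15, 35))
}
toy_demand <- function() {
  d <- tibble::tibble(id = c("d1", "d2", "d3"), x = 0, y = 0,
                      population = c(100, 200, 500), region = "R1")
  class(d) <- c("demand_points", class(d))
  d
}

test_that("coverage table bins population into half-open time bands", {
  cov <- coverage_table(toy_nearest(), toy_demand())
  expect_equal(cov$bands$population, c(100, 200, 0, 500))
  expect_equal(cov$within$population, 300)
  expect_equal(cov$within$share, 37.5)
  expect_equal(cov$beyond$share, 62.5)
  expect_equal(sum(cov$bands$population), cov$total)

  # all demand co-located with facilities: first band holds everything
  near0 <- tibble::tibble(demand_id = c("d1", "d2", "d3"), minutes = 0)
  cov0 <- coverage_table(near0, toy_demand())
  expect_equal(cov0$bands$population, c(800, 0, 0, 0))
  expect_equal(cov0$beyond$population, 0)

  # unreachable demand lands in the beyond band
  nearu <- tibble::tibble(demand_id = c("d1", "d2", "d3"),
                          minutes = c(5, Inf, Inf))
  covu <- coverage_table(nearu, toy_demand())
  expect_equal(covu$beyond$population, 700)

  expect_error(coverage_table(toy_nearest(), toy_demand()[0, ]),
               class = "catchfca_contract_error")
})

test_that("band boundaries are right-closed", {
  near <- tibble::tibble(demand_id = c("d1", "d2", "d3"),
                         minutes = c(10, 20, 30))
  cov <- coverage_table(near, toy_demand())
  expect_equal(cov$bands$population, c(100, 200, 500, 0))
})

test_that("mean nearest time is population-weighted", {
  expect_equal(mean_nearest_time(toy_nearest(), toy_demand()), 26.25)
  one <- tibble::tibble(demand_id = "d", minutes = 29)
  dem <- toy_demand()[1, ]; dem$id <- "d"
  expect_equal(mean_nearest_time(one, dem), 29)
  # equal populations at 29 and 41 minutes average to 35
  two <- tibble::tibble(demand_id = c("a", "b"), minutes = c(29, 41))
  dem2 <- tibble::tibble(id = c("a", "b"), x = 0, y = 0,
                         population = c(50, 50), region = "R")
  expect_equal(mean_nearest_time(two, dem2), 35)
})

test_that("unreachable demand follows the exclusion policy", {
  near <- tibble::tibble(demand_id = c("d1", "d2", "d3"),
                         minutes = c(5, 15, Inf))
  expect_error(mean_nearest_time(near, toy_demand()),
               class = "catchfca_unreachable_demand")
  expect_warning(
    m <- mean_nearest_time(near, toy_demand(), exclude_unreachable = TRUE),
    class = "catchfca_unreachable_excluded"
  )
  expect_equal(m, (100 * 5 + 200 * 15) / 300)
  zero <- toy_demand(); zero$population <- 0
  expect_error(mean_nearest_time(toy_nearest(), zero),
               class = "catchfca_contract_error")
})

test_that("regional summary computes descriptive statistics and interval counts", {
  surf <- tibble::tibble(
    demand_id = c("a", "b", "c"), region = "R1",
    population = c(10, 10, 10), std = c(0, 0.42, 1)
  )
  rs <- regional_summary(surf)
  expect_equal(rs$mean, mean(c(0, 0.42, 1)), tolerance = 1e-12)
  expect_equal(round(rs$mean, 4), 0.4733)
  expect_equal(rs$max, 1)
  expect_equal(rs$sd, sd(c(0, 0.42, 1)), tolerance = 1e-12)

  # constant indices have zero spread
  flat <- tibble::tibble(demand_id = c("a", "b"), region = "R", population = 5,
                         std = 0.3)
  expect_equal(regional_summary(flat)$sd, 0)

  # interval populations: first interval closed at 0, others (lo, hi]
  iv <- tibble::tibble(demand_id = c("a", "b"), region = "R",
                       population = c(50, 70), std = c(0.1, 0.3))
  rsi <- regional_summary(iv)
  expect_equal(rsi$pop_0_0.25, 50)
  expect_equal(rsi$pop_0.25_0.5, 70)
  expect_equal(rsi$pop_0_0.25 + rsi$pop_0.25_0.5 + rsi$pop_0.5_0.75 +
                 rsi$pop_0.75_1, rsi$population)

  # population weighting flag
  rw <- regional_summary(iv, weighted = TRUE)
  expect_equal(rw$mean, (50 * 0.1 + 70 * 0.3) / 120, tolerance = 1e-12)
})

test_that("scenario comparison reports exact after-minus-before deltas", {
  mk <- function(minutes, pops) {
    near <- tibble::tibble(demand_id = sprintf("d%d", seq_along(minutes)),
                           minutes = minutes)
    dem <- tibble::tibble(id = near$demand_id, x = 0, y = 0,
                          population = pops, region = "R")
    scenario_result(coverage_table(near, dem), mean_nearest_time(near, dem))
  }
  before <- mk(c(5, 15, 35), c(100, 200, 500))
  after <- mk(c(5, 25, 45), c(100, 200, 500))
  cmp <- compare_scenarios(before, after)
  expect_equal(cmp$bands$count_delta,
               after$coverage$bands$population - before$coverage$bands$population)
  expect_equal(cmp$bands$share_delta_pp,
               after$coverage$bands$share - before$coverage$bands$share)
  expect_equal(cmp$mean_minutes$delta,
               after$mean_minutes - before$mean_minutes)

  # identical scenarios: all deltas zero
  same <- compare_scenarios(before, before)
  expect_true(all(same$bands$count_delta == 0))
  expect_true(all(same$bands$share_delta_pp == 0))
  expect_equal(same$mean_minutes$delta, 0)

  # mismatched band edges are rejected
  near <- tibble::tibble(demand_id = c("d1", "d2", "d3"),
                         minutes = c(5, 15, 35))
  dem <- toy_demand()
  odd <- scenario_result(coverage_table(near, dem, bands = c(15, 30)),
                         mean_nearest_time(near, dem))
  expect_error(compare_scenarios(before, odd),
               class = "catchfca_contract_error")
})

test_that("band populations always partition the total population", {
  withr::with_seed(909, {
    for (rep in 1:10) {
      n <- sample(5:40, 1)
      near <- tibble::tibble(
        demand_id = sprintf("d%d", 1:n),
        minutes = ifelse(runif(n) < 0.1, Inf, runif(n, 0, 60))
      )
      dem <- tibble::tibble(id = near$demand_id, x = 0, y = 0,
                            population = sample(0:1000, n, TRUE), region = "R")
      cov <- coverage_table(near, dem)
      expect_equal(sum(cov$bands$population), sum(dem$population))
      if (sum(dem$population) > 0) {
        expect_equal(sum(cov$bands$share), 100, tolerance = 1e-9)
      }
    }
  })
})
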