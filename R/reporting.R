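band_labels <- function(edges) {
  c(sprintf("%g-%g", c(0, head(edges, -1)), edges), sprintf(">%g", edges[length(edges)]))
}

#' Isochrone population-coverage table
#'
#' Tabulates the population by nearest-facility travel-time band. Bands are
#' half-open `(lower, upper]` with `t = 0` counted in the first band;
#' everything above the last edge — including demand unreachable from every
#' facility — falls in the beyond-catchment band. Shares are percentages of
#' the total population, kept unrounded internally and reported to one
#' decimal when printed or exported.
#'
#' @param nearest Tibble `demand_id`, `minutes` from
#'   [nearest_facility_time()] (`Inf` = unreachable).
#' @param demand A `demand_points` tibble; every demand id must be present
#'   in `nearest`.
#' @param bands Increasing band edges in minutes (default `c(10, 20, 30)`).
#' @return An object of class `coverage_table`: list with `bands` (tibble
#'   `band`, `lower`, `upper`, `population`, `share`), `total`, `within`
#'   and `beyond` (population and share at the last edge).
#' @export
coverage_table <- function(nearest, demand, bands = c(10, 20, 30)) {
  if (nrow(demand) == 0) {
    stop_catchfca("coverage_table needs at least one demand point", "contract_error")
  }
  if (!all(demand$id %in% nearest$demand_id)) {
    stop_catchfca("every demand id must appear in the nearest-time table",
                  "contract_error")
  }
  stopifnot(all(diff(bands) > 0), all(bands > 0))
  t <- nearest$minutes[match(demand$id, nearest$demand_id)]
  idx <- findInterval(t, c(0, bands), left.open = TRUE)
  idx[t == 0] <- 1L                       # co-location counts as covered
  idx[!is.finite(t)] <- length(bands) + 1L
  pop <- vapply(seq_len(length(bands) + 1L), function(b) {
    sum(demand$population[idx == b])
  }, numeric(1))
  total <- sum(demand$population)
  share <- if (total > 0) pop / total * 100 else rep(NA_real_, length(pop))
  tab <- tibble::tibble(
    band = band_labels(bands),
    lower = c(0, bands),
    upper = c(bands, Inf),
    population = pop,
    share = share
  )
  n_in <- length(bands)
  structure(
    list(
      bands = tab,
      total = total,
      within = list(population = sum(pop[seq_len(n_in)]),
                    share = sum(share[seq_len(n_in)])),
      beyond = list(population = pop[n_in + 1L], share = share[n_in + 1L]),
      edges = bands
    ),
    class = "coverage_table"
  )
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("<coverage_table> population by nearest-facility travel time\n")
  tab <- x$bands
  tab$share <- round(tab$share, 1)
  print(as.data.frame(tab[, c("band", "population", "share")]), row.names = FALSE)
  cat(sprintf("within %g min: %s (%.1f%%)   beyond: %s (%.1f%%)\n",
              x$edges[length(x$edges)],
              format(x$within$population, big.mark = ","), x$within$share,
              format(x$beyond$population, big.mark = ","), x$beyond$share))
  invisible(x)
}

#' Population-weighted mean nearest-facility travel time
#'
#' @param nearest Tibble `demand_id`, `minutes`.
#' @param demand A `demand_points` tibble.
#' @param exclude_unreachable If `TRUE`, unreachable demand (`Inf` minutes)
#'   is dropped with a warning reporting the excluded population; if
#'   `FALSE` (default) unreachable entries are an error.
#' @return Mean minutes, weighted by population.
#' @export
mean_nearest_time <- function(nearest, demand, exclude_unreachable = FALSE) {
  t <- nearest$minutes[match(demand$id, nearest$demand_id)]
  pop <- demand$population
  bad <- !is.finite(t)
  if (any(bad)) {
    if (!exclude_unreachable) {
      stop_catchfca(
        sprintf("%d demand point(s) unreachable from every facility; set exclude_unreachable = TRUE to drop them",
                sum(bad)),
        "unreachable_demand"
      )
    }
    warn_catchfca(
      sprintf("excluding %d unreachable demand point(s) (population %g) from the mean",
              sum(bad), sum(pop[bad])),
      "unreachable_excluded"
    )
    t <- t[!bad]; pop <- pop[!bad]
  }
  if (sum(pop) <= 0) {
    stop_catchfca("total population is zero; mean travel time undefined", "contract_error")
  }
  sum(t * pop) / sum(pop)
}

#' Regional summary of standardized accessibility
#'
#' Per-region descriptive statistics of the standardized index over demand
#' units (mean, max, sample standard deviation) and population totals per
#' index interval `[0, 0.25], (0.25, 0.5], (0.5, 0.75], (0.75, 1]`. The
#' statistics are unweighted across demand units by default; set
#' `weighted = TRUE` for population-weighted mean and standard deviation.
#'
#' @param result Accessibility surface tibble with `region`, `population`
#'   and `std` columns ([accessibility_surface()]).
#' @param demand Optional `demand_points` tibble supplying `region` and
#'   `population` when `result` lacks them.
#' @param weighted Population-weight the mean and standard deviation.
#' @param intervals Increasing upper edges of the index intervals.
#' @return A tibble of class `regional_summary`: one row per region with
#'   `mean`, `max`, `sd`, `n_units`, `population` and one `pop_*` column
#'   per interval.
#' @export
regional_summary <- function(result, demand = NULL, weighted = FALSE,
                             intervals = c(0.25, 0.5, 0.75, 1)) {
  if (!is.null(demand)) {
    result <- dplyr::left_join(
      dplyr::select(result, -dplyr::any_of(c("region", "population"))),
      dplyr::select(demand, dplyr::all_of(c("id", "region", "population"))),
      by = c(demand_id = "id")
    )
  }
  stopifnot(all(c("region", "population", "std") %in% names(result)))
  empty <- setdiff(unique(result$region), result$region[!is.na(result$std)])
  if (length(empty) > 0) {
    warn_catchfca(sprintf("region(s) with no scored demand omitted: %s",
                          paste(empty, collapse = ", ")),
                  "empty_region")
    result <- result[!result$region %in% empty, , drop = FALSE]
  }
  iv_idx <- function(z) {
    i <- findInterval(z, c(0, intervals), left.open = TRUE)
    i[z == 0] <- 1L                       # first interval closed at 0
    i
  }
  stats_one <- function(df) {
    z <- df$std; p <- df$population
    if (weighted && sum(p) > 0) {
      m <- sum(z * p) / sum(p)
      s <- sqrt(sum(p * (z - m)^2) / sum(p))
    } else {
      m <- mean(z)
      s <- if (length(z) > 1) sd(z) else 0
    }
    iv <- iv_idx(z)
    pops <- vapply(seq_along(intervals), function(b) sum(p[iv == b]), numeric(1))
    names(pops) <- sprintf("pop_%g_%g", c(0, head(intervals, -1)), intervals)
    dplyr::bind_cols(
      tibble::tibble(mean = m, max = max(z), sd = s,
                     n_units = length(z), population = sum(p)),
      tibble::as_tibble(as.list(pops))
    )
  }
  out <- result |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(~ stats_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$region)
  structure(out, intervals = intervals, weighted = weighted,
            class = c("regional_summary", class(out)))
}

#' Compare two accessibility scenarios
#'
#' Takes the result bundles of a "before" and an "after" scenario (as built
#' by [scenario_result()]) and reports band-by-band population deltas,
#' share deltas in percentage points, the mean nearest-time difference and
#' per-region mean-index deltas. All deltas are `after - before` exactly;
#' a positive count delta can coexist with a negative share delta when the
#' two scenarios have different total populations.
#'
#' @param before,after Lists with elements `coverage` ([coverage_table()]),
#'   `mean_minutes` (scalar) and optionally `regional`
#'   ([regional_summary()]); see [scenario_result()].
#' @return Object of class `scenario_comparison`: list with `bands` tibble
#'   (`count_delta`, `share_delta_pp`), `mean_minutes`
#'   (before/after/delta) and `regional` tibble (`mean_delta`).
#' @export
compare_scenarios <- function(before, after) {
  cb <- before$coverage; ca <- after$coverage
  stopifnot(inherits(cb, "coverage_table"), inherits(ca, "coverage_table"))
  if (!isTRUE(all.equal(cb$edges, ca$edges))) {
    stop_catchfca("scenario coverage tables use different band edges", "contract_error")
  }
  bands <- tibble::tibble(
    band = cb$bands$band,
    population_before = cb$bands$population,
    population_after = ca$bands$population,
    count_delta = ca$bands$population - cb$bands$population,
    share_before = cb$bands$share,
    share_after = ca$bands$share,
    share_delta_pp = ca$bands$share - cb$bands$share
  )
  mean_minutes <- list(before = before$mean_minutes, after = after$mean_minutes,
                       delta = after$mean_minutes - before$mean_minutes)
  regional <- NULL
  if (!is.null(before$regional) && !is.null(after$regional)) {
    rb <- before$regional; ra <- after$regional
    if (!setequal(rb$region, ra$region)) {
      stop_catchfca("scenarios cover different region sets", "contract_error")
    }
    regional <- dplyr::inner_join(
      dplyr::select(tibble::as_tibble(rb), "region", mean_before = "mean"),
      dplyr::select(tibble::as_tibble(ra), "region", mean_after = "mean"),
      by = "region"
    ) |>
      dplyr::mutate(mean_delta = .data$mean_after - .data$mean_before)
  }
  structure(list(bands = bands, mean_minutes = mean_minutes, regional = regional),
            class = "scenario_comparison")
}

#' Bundle the result surfaces of one scenario for comparison
#'
#' @param coverage A [coverage_table()].
#' @param mean_minutes Population-weighted mean nearest time (minutes).
#' @param regional Optional [regional_summary()].
#' @return List of class `scenario_result`.
#' @export
scenario_result <- function(coverage, mean_minutes, regional = NULL) {
  structure(list(coverage = coverage, mean_minutes = mean_minutes,
                 regional = regional),
            class = "scenario_result")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison> after - before\n")
  tab <- x$bands
  tab$share_delta_pp <- round(tab$share_delta_pp, 1)
  print(as.data.frame(tab[, c("band", "count_delta", "share_delta_pp")]),
        row.names = FALSE)
  cat(sprintf("mean nearest time: %.2f -> %.2f min (delta %+.2f)\n",
              x$mean_minutes$before, x$mean_minutes$after, x$mean_minutes$delta))
  invisible(x)
}

#' Export a coverage table as CSV (shares to one decimal)
#' @param x A `coverage_table`.
#' @param path Output CSV path.
#' @export
write_coverage_table <- function(x, path) {
  stopifnot(inherits(x, "coverage_table"))
  tab <- x$bands
  tab$share <- round(tab$share, 1)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Export a regional summary as CSV (index statistics to three decimals)
#' @param x A `regional_summary`.
#' @param path Output CSV path.
#' @export
write_regional_summary <- function(x, path) {
  stopifnot(inherits(x, "regional_summary"))
  tab <- tibble::as_tibble(x)
  tab$mean <- round(tab$mean, 3)
  tab$max <- round(tab$max, 3)
  tab$sd <- round(tab$sd, 3)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Export a scenario comparison as CSV plus a text summary
#' @param x A `scenario_comparison`.
#' @param csv_path,txt_path Output paths.
#' @export
write_comparison <- function(x, csv_path, txt_path = NULL) {
  stopifnot(inherits(x, "scenario_comparison"))
  tab <- x$bands
  tab$share_before <- round(tab$share_before, 1)
  tab$share_after <- round(tab$share_after, 1)
  tab$share_delta_pp <- round(tab$share_delta_pp, 1)
  readr::write_csv(tab, csv_path, progress = FALSE)
  if (!is.null(txt_path)) {
    lines <- c(
      "Scenario comparison (after - before)",
      sprintf("  beyond-catchment population: %+g (%+.1f p.p.)",
              tab$count_delta[nrow(tab)], tab$share_delta_pp[nrow(tab)]),
      sprintf("  mean nearest-facility time: %.2f -> %.2f min (delta %+.2f)",
              x$mean_minutes$before, x$mean_minutes$after, x$mean_minutes$delta)
    )
    if (!is.null(x$regional)) {
      lines <- c(lines, "  mean standardized index by region:",
                 sprintf("    %s: %+.4f", x$regional$region, x$regional$mean_delta))
    }
    writeLines(lines, txt_path)
  }
  invisible(csv_path)
}
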