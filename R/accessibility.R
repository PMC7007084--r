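#' Stepped distance-decay scheme for the floating catchment
#'
#' Defines the catchment size `C` (minutes), the zone breakpoints
#' `D_r = (C/3, 2C/3, C)` and the per-zone weights applied to both steps of
#' the E2SFCA. The defaults are a 30-minute catchment with zones
#' (0,10], (10,20], (20,30] and weights 1, 0.42, 0.03 — a stepped
#' discretisation of a Gaussian decay with parameter `beta = 1.15`. `beta`
#' is carried as provenance metadata only; the weights are the operative
#' constants, and alternative weight vectors are accepted.
#'
#' @param catchment Catchment size `C` in minutes.
#' @param breakpoints Strictly increasing zone upper bounds ending at
#'   `catchment`; default `c(C/3, 2C/3, C)`.
#' @param weights Strictly decreasing per-zone weights with `weights[1] = 1`.
#' @param beta Decay parameter recorded as metadata.
#' @return An object of class `decay_scheme`.
#' @examples
#' decay_scheme()          # the 30-minute, (1, 0.42, 0.03) default
#' decay_scheme(catchment = 60)
#' @export
decay_scheme <- function(catchment = 30,
                         breakpoints = catchment * seq_along(weights) / length(weights),
                         weights = c(1, 0.42, 0.03),
                         beta = 1.15) {
  stopifnot(is.numeric(catchment), length(catchment) == 1, catchment > 0)
  if (length(breakpoints) != length(weights)) {
    stop_catchfca("breakpoints and weights must have equal length", "scheme_error")
  }
  if (any(diff(c(0, breakpoints)) <= 0) ||
      abs(breakpoints[length(breakpoints)] - catchment) > 1e-9) {
    stop_catchfca("breakpoints must be strictly increasing and end at the catchment",
                  "scheme_error")
  }
  if (weights[1] != 1 || any(diff(weights) >= 0) || any(weights < 0)) {
    stop_catchfca("weights must start at 1 and be strictly decreasing and nonnegative",
                  "scheme_error")
  }
  structure(
    list(catchment = catchment, breakpoints = as.numeric(breakpoints),
         weights = as.numeric(weights), beta = beta),
    class = "decay_scheme"
  )
}

#' @export
print.decay_scheme <- function(x, ...) {
  cat(sprintf("<decay_scheme> C = %g min; zones (%s]; weights %s; beta = %g\n",
              x$catchment,
              paste(c(0, x$breakpoints), collapse = ", "),
              paste(x$weights, collapse = "/"), x$beta))
  invisible(x)
}

#' Assign a travel time to a decay zone
#'
#' Zone `r` is the half-open interval `(D_{r-1}, D_r]` with `D_0 = 0`
#' (right-closed boundaries: `t = 10` falls in zone 1 of the default
#' scheme). Times beyond the catchment return `NA` ("none"). `t = 0`
#' (co-located demand and facility) is assigned to zone 1 by convention so
#' that co-location never loses access.
#'
#' @param t Travel time in minutes, >= 0 (vectorised).
#' @param scheme A [decay_scheme()].
#' @return Integer zone (1-based) or `NA` when `t` exceeds the catchment.
#' @export
assign_zone <- function(t, scheme = decay_scheme()) {
  stopifnot(inherits(scheme, "decay_scheme"))
  if (any(t < 0, na.rm = TRUE)) {
    stop_catchfca("travel time must be nonnegative", "validation_error")
  }
  zone <- findInterval(t, c(0, scheme$breakpoints), left.open = TRUE,
                       rightmost.closed = FALSE)
  zone[t == 0] <- 1L                      # co-location convention
  zone[t > scheme$catchment] <- NA_integer_
  as.integer(zone)
}

#' Distance-decay weight of a zone
#'
#' @param zone Integer zone from [assign_zone()]; `NA` (beyond catchment)
#'   maps to weight 0.
#' @param scheme A [decay_scheme()].
#' @return Numeric weight.
#' @export
decay_weight <- function(zone, scheme = decay_scheme()) {
  stopifnot(inherits(scheme, "decay_scheme"))
  bad <- !is.na(zone) & (zone < 1 | zone > length(scheme$weights))
  if (any(bad)) {
    stop_catchfca(sprintf("unknown zone token: %s",
                          paste(unique(zone[bad]), collapse = ", ")),
                  "scheme_error")
  }
  w <- scheme$weights[zone]
  w[is.na(zone)] <- 0
  w
}

time_decay_weight <- function(t, scheme) {
  decay_weight(assign_zone(t, scheme), scheme)
}

#' Step-1 supply-to-population ratio of one facility
#'
#' The floating-catchment first step: the facility's supply (physician
#' count) divided by the decay-weighted population inside its catchment,
#' `R_j = S_j / sum_k P_k W(d_kj)`. A facility whose weighted catchment
#' population is zero gets `R_j = 0` with a warning (it is excluded from
#' the supply-conservation identity) rather than an error.
#'
#' @param facility One-row facilities tibble (or a list with `id`,
#'   `physicians`).
#' @param ttm A `travel_time_matrix` from [od_matrix()].
#' @param demand A `demand_points` tibble.
#' @param scheme A [decay_scheme()].
#' @return The ratio `R_j` (physicians per decay-weighted person).
#' @export
facility_ratio <- function(facility, ttm, demand, scheme = decay_scheme()) {
  rows <- ttm[ttm$facility_id == facility$id, , drop = FALSE]
  w <- time_decay_weight(rows$minutes, scheme)
  pop <- demand$population[match(rows$demand_id, demand$id)]
  denom <- sum(pop * w)
  if (denom <= 0) {
    if (facility$physicians > 0) {
      warn_catchfca(
        sprintf("facility %s has zero weighted catchment population; ratio set to 0",
                facility$id),
        "empty_catchment"
      )
    }
    return(0)
  }
  facility$physicians / denom
}

#' Enhanced two-step floating catchment area accessibility index
#'
#' Step 1 computes, for every active facility `j`, the ratio of its supply
#' to the decay-weighted population within its catchment,
#' `R_j = S_j / sum_k P_k W(d_kj)`. Step 2 sums the decay-weighted ratios
#' of the facilities reachable from each demand point `i`,
#' `A_i = sum_{j : d_ij <= C} R_j W(d_ij)`. Both steps use the same stepped
#' decay scheme and travel-time matrix, which yields the exact conservation
#' identity `sum_i P_i A_i = sum_j S_j` over facilities with a positive
#' weighted catchment population. Demand with no facility within the
#' catchment gets `A_i = 0`.
#'
#' @param ttm A `travel_time_matrix` whose cutoff equals `scheme$catchment`.
#' @param demand A `demand_points` tibble.
#' @param facilities A `facilities` tibble; only rows with `active = TRUE`
#'   contribute.
#' @param scheme A [decay_scheme()].
#' @return Tibble `demand_id`, `raw` (the index `A_i`, physicians per
#'   person), with the per-facility step-1 ratios in attribute
#'   `facility_ratios`.
#' @export
e2sfca <- function(ttm, demand, facilities, scheme = decay_scheme()) {
  stopifnot(inherits(scheme, "decay_scheme"))
  cutoff <- attr(ttm, "cutoff")
  if (!is.null(cutoff) && abs(cutoff - scheme$catchment) > 1e-9) {
    stop_catchfca("travel-time matrix cutoff differs from the scheme catchment",
                  "scheme_error")
  }
  act <- facilities[facilities$active, , drop = FALSE]
  tt <- tibble::as_tibble(ttm)
  tt <- tt[tt$facility_id %in% act$id, , drop = FALSE]
  tt$w <- time_decay_weight(tt$minutes, scheme)
  tt$pop <- demand$population[match(tt$demand_id, demand$id)]

  denom <- tt |>
    dplyr::group_by(.data$facility_id) |>
    dplyr::summarise(denom = sum(.data$pop * .data$w), .groups = "drop")
  ratios <- tibble::tibble(facility_id = act$id, supply = act$physicians) |>
    dplyr::left_join(denom, by = "facility_id") |>
    dplyr::mutate(
      denom = dplyr::coalesce(.data$denom, 0),
      ratio = dplyr::if_else(.data$denom > 0, .data$supply / .data$denom, 0)
    )
  starved <- ratios$facility_id[ratios$denom <= 0 & ratios$supply > 0]
  if (length(starved) > 0) {
    warn_catchfca(
      sprintf("facility(ies) with zero weighted catchment population: %s",
              paste(starved, collapse = ", ")),
      "empty_catchment"
    )
  }

  tt$ratio <- ratios$ratio[match(tt$facility_id, ratios$facility_id)]
  acc <- tt |>
    dplyr::group_by(.data$demand_id) |>
    dplyr::summarise(raw = sum(.data$ratio * .data$w), .groups = "drop")
  out <- tibble::tibble(demand_id = demand$id) |>
    dplyr::left_join(acc, by = "demand_id") |>
    dplyr::mutate(raw = dplyr::coalesce(.data$raw, 0))
  attr(out, "facility_ratios") <-
    setNames(ratios$ratio, ratios$facility_id)
  attr(out, "facility_table") <- ratios
  out
}

#' Min-max standardization of accessibility scores
#'
#' Linear rescale of the raw index to `[0, 1]`:
#' `Z = (A - min A) / (max A - min A)` across all demand units in the run
#' (one global min-max). When all values are equal the rescale is undefined
#' and every value is mapped to 0 with a warning.
#'
#' @param raw Named numeric vector or tibble with columns `demand_id`, `raw`.
#' @return Same shape as the input with values in `[0, 1]` (column `std`
#'   for tibble input).
#' @export
standardize <- function(raw) {
  if (is.data.frame(raw)) {
    vals <- setNames(raw$raw, raw$demand_id)
    std <- standardize(vals)
    raw$std <- as.numeric(std)
    return(raw)
  }
  if (length(raw) == 0) {
    stop_catchfca("cannot standardize an empty value set", "contract_error")
  }
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) {
    warn_catchfca("all accessibility values identical; standardized scores set to 0",
                  "degenerate_standardization")
    return(setNames(rep(0, length(raw)), names(raw)))
  }
  (raw - lo) / (hi - lo)
}

#' Full accessibility surface for one scenario
#'
#' Convenience wrapper running [e2sfca()] and [standardize()] and attaching
#' nearest-facility times: the per-demand result table most analyses want.
#'
#' @inheritParams e2sfca
#' @param nearest Tibble `demand_id`, `minutes` from
#'   [nearest_facility_time()] (optional).
#' @return Tibble `demand_id`, `region`, `population`, `raw`, `std` and,
#'   when `nearest` is given, `nearest_minutes`.
#' @export
accessibility_surface <- function(ttm, demand, facilities,
                                  scheme = decay_scheme(), nearest = NULL) {
  res <- e2sfca(ttm, demand, facilities, scheme)
  res <- standardize(res)
  out <- tibble::tibble(
    demand_id = demand$id,
    region = demand$region,
    population = demand$population
  ) |>
    dplyr::left_join(res, by = "demand_id")
  if (!is.null(nearest)) {
    out$nearest_minutes <- nearest$minutes[match(out$demand_id, nearest$demand_id)]
  }
  attr(out, "facility_ratios") <- attr(res, "facility_ratios")
  attr(out, "facility_table") <- attr(res, "facility_table")
  out
}
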