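#' Round a nonnegative numeric vector to integers preserving the total
#'
#' Largest-remainder (Hamilton) rounding: floors every value, then distributes
#' the remaining units to the entries with the largest fractional parts.
#' Ties on the fractional part are broken by position, so the result is
#' deterministic for a fixed input order.
#'
#' @param x Nonnegative numeric vector.
#' @param total Target integer sum; defaults to `round(sum(x))`.
#' @return Integer vector of the same length summing exactly to `total`.
#' @keywords internal
largest_remainder_round <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  if (length(x) == 0L) return(integer(0))
  base <- floor(x)
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    frac <- x - base
    idx <- order(frac, seq_along(x), decreasing = c(TRUE, FALSE), method = "radix")
    take <- idx[seq_len(min(short, length(x)))]
    base[take] <- base[take] + 1
    short <- short - length(take)
    # pathological case: still short after one unit each (total >> sum(x))
    while (short > 0L) {
      k <- min(short, length(x))
      base[idx[seq_len(k)]] <- base[idx[seq_len(k)]] + 1
      short <- short - k
    }
  } else if (short < 0L) {
    # target below the floored sum: remove units from smallest fractions
    frac <- x - base
    idx <- order(frac, seq_along(x), method = "radix")
    for (i in idx) {
      if (short == 0L) break
      if (base[i] > 0) {
        base[i] <- base[i] - 1
        short <- short + 1L
      }
    }
  }
  as.integer(base)
}

#' Euclidean distance between one point and a set of points
#' @keywords internal
euclid_dist <- function(x, y, xs, ys) {
  sqrt((xs - x)^2 + (ys - y)^2)
}

stop_catchfca <- function(msg, class) {
  rlang::abort(msg, class = paste0("catchfca_", class))
}

warn_catchfca <- function(msg, class) {
  rlang::warn(msg, class = paste0("catchfca_", class))
}
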