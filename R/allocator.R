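#' Normalise benefit maps per objective
#'
#' For each objective the raw benefits are min-max rescaled to [0, 1] using
#' the global minimum and maximum over all convertible cells and all four
#' categories, so the per-cell weighted sum of Eq.-style scalarization is
#' well-scaled across objectives. A constant layer normalises to all zeros
#' with a warning.
#'
#' @param maps a [assemble_benefit_maps()] result.
#' @return an object of class `normalized_benefits` carrying the normalised
#'   array `b` (`cells x 4 x 3`), the raw array, the per-objective bounds used,
#'   and the grid metadata needed by the allocator.
#' @export
normalize_benefits <- function(maps) {
  stopifnot(inherits(maps, "benefit_maps"))
  if (!all(is.finite(maps$raw[maps$convertible, , ])))
    stop("input error: non-finite benefit values on convertible cells", call. = FALSE)
  b <- maps$raw
  bounds <- matrix(NA_real_, 2, 3, dimnames = list(c("min", "max"), objectives()))
  for (o in 1:3) {
    vals <- maps$raw[maps$convertible, , o]
    rng <- range(vals)
    bounds[, o] <- rng
    if (rng[1] == rng[2]) {
      warning(sprintf("objective '%s' is constant; normalised to 0", objectives()[o]))
      b[, , o] <- 0
    } else {
      b[, , o] <- (maps$raw[, , o] - rng[1]) / (rng[2] - rng[1])
    }
  }
  structure(list(b = b, raw = maps$raw, bounds = bounds,
                 n_rows = maps$n_rows, n_cols = maps$n_cols,
                 cell_area = maps$cell_area,
                 current_use = maps$current_use,
                 convertible = maps$convertible),
            class = "normalized_benefits")
}

#' Per-cell weighted benefit under a weighting
#'
#' The weighted-sum scalarization: for every cell n and category k,
#' `b[n,k] = bC[n,k] w_C/100 + bP[n,k] w_P/100 + bB[n,k] w_B/100`, a value in
#' [0, 1] since the weights are convex and the inputs normalised.
#'
#' @param norm a [normalize_benefits()] result.
#' @param w a weighting (integer percents summing to 100).
#' @return numeric matrix `cells x 4`.
#' @export
weighted_benefit <- function(norm, w) {
  stopifnot(inherits(norm, "normalized_benefits"))
  w <- as_weight(w)
  layer <- function(o) {
    m <- norm$b[, , o, drop = FALSE]
    dim(m) <- dim(norm$b)[1:2]   # keep matrix shape on single-cell grids
    m
  }
  out <- (layer(1) * w[1] + layer(2) * w[2] + layer(3) * w[3]) / 100
  colnames(out) <- lu_categories()
  out
}

# tie-ruled per-cell argmax of a cells x 4 weighted-benefit matrix:
# prefer the incumbent category, then the fixed category order.
argmax_with_ties <- function(bw, current, tie_rule = "current_first") {
  best <- pmax(bw[, 1], bw[, 2], bw[, 3], bw[, 4])
  is_max <- bw == best
  k <- max.col(is_max, ties.method = "first")
  if (tie_rule == "current_first") {
    keep <- is_max[cbind(seq_along(current), current)]
    k[keep] <- current[keep]
  }
  k
}

# build a scenario object from an assignment
make_scenario <- function(assignment, norm, w, budget = NA_real_, seed = NA_integer_) {
  conv <- norm$convertible
  converted <- conv & assignment != norm$current_use
  sc <- structure(list(assignment = assignment, weighting = w,
                       budget = budget, seed = seed, converted = converted,
                       conversion_rate = mean(converted[conv]),
                       performance_raw = NULL),
                  class = "scenario")
  sc$performance_raw <- evaluate_scenario(sc, norm)
  sc
}

#' Optimal land allocation for one weighting
#'
#' Chooses, independently for every convertible cell, the category with the
#' maximum weighted benefit. Because the aggregate objective is a sum over
#' cells, this per-cell argmax is the global optimum over all possible
#' allocations. Ties prefer the incumbent category (avoiding phantom
#' conversions at zero gain), then the fixed order arable < pasture <
#' plantation < semi-natural. Non-convertible cells keep their current use.
#'
#' @param norm a [normalize_benefits()] result.
#' @param w a weighting.
#' @param tie_rule `"current_first"` (default) or `"fixed_order"`.
#' @return an object of class `scenario`: the per-cell assignment, the
#'   conversion mask and rate, and the raw performance triple.
#' @export
optimal_allocation <- function(norm, w, tie_rule = c("current_first", "fixed_order")) {
  stopifnot(inherits(norm, "normalized_benefits"))
  tie_rule <- match.arg(tie_rule)
  w <- as_weight(w)
  bw <- weighted_benefit(norm, w)
  k <- argmax_with_ties(bw, norm$current_use, tie_rule)
  assignment <- ifelse(norm$convertible, k, norm$current_use)
  make_scenario(assignment, norm, w)
}

#' Budget-constrained greedy allocation
#'
#' Cells are converted successively from most to least beneficial until the
#' conversion budget is met. The merit of a cell is its improvement delta:
#' the weighted benefit of its best category minus that of keeping its
#' current use. Only cells with a strictly positive delta are candidates, so
#' the realized conversion rate can fall below the budget ("it is best to
#' maintain the existing land-use"). The number of conversions is
#' `floor(budget * n_convertible)` (never exceeding the budget); equally
#' beneficial cells at the cut are ordered by a seeded uniform shuffle.
#'
#' @param norm a [normalize_benefits()] result.
#' @param w a weighting.
#' @param budget fraction of convertible cells allowed to change, in [0, 1].
#' @param seed integer seed for random tie-breaking among equal deltas.
#' @param tie_rule argmax tie rule, as in [optimal_allocation()].
#' @return a `scenario`.
#' @export
budget_allocation <- function(norm, w, budget, seed = 1L,
                              tie_rule = c("current_first", "fixed_order")) {
  stopifnot(inherits(norm, "normalized_benefits"))
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(budget) || length(budget) != 1L || budget < 0 || budget > 1)
    stop("config error: budget must lie in [0, 1]", call. = FALSE)
  w <- as_weight(w)
  bw <- weighted_benefit(norm, w)
  idx <- seq_along(norm$current_use)
  kstar <- argmax_with_ties(bw, norm$current_use, tie_rule)
  delta <- bw[cbind(idx, kstar)] - bw[cbind(idx, norm$current_use)]
  pool <- which(norm$convertible & delta > 0)
  m <- floor(budget * sum(norm$convertible))
  chosen <- integer(0)
  if (m > 0 && length(pool)) {
    shuffle <- with_seed(seed, sample.int(length(pool)))
    ord <- pool[order(-delta[pool], shuffle)]
    chosen <- ord[seq_len(min(m, length(ord)))]
  }
  assignment <- norm$current_use
  assignment[chosen] <- kstar[chosen]
  make_scenario(assignment, norm, w, budget = budget, seed = as.integer(seed))
}

#' Aggregate raw performance of a scenario
#'
#' Sums, per objective, the raw benefit of the assigned category over all
#' convertible cells: the scenario's performance triple in native units
#' (t CO2-eq/yr, GBP/yr, summed biodiversity indicator).
#'
#' @param scenario a `scenario` (or any list with an `assignment` field).
#' @param maps a `benefit_maps` or `normalized_benefits` object (the raw
#'   array is used).
#' @return named numeric vector `carbon`, `production`, `biodiversity`.
#' @export
evaluate_scenario <- function(scenario, maps) {
  raw <- maps$raw
  conv <- maps$convertible
  assignment <- scenario$assignment
  if (length(assignment) != dim(raw)[1])
    stop("alignment error: assignment does not match the benefit grid", call. = FALSE)
  idx <- which(conv)
  out <- vapply(1:3, function(o) {
    layer <- raw[, , o, drop = FALSE]
    dim(layer) <- dim(raw)[1:2]   # keep matrix shape on single-cell grids
    sum(layer[cbind(idx, assignment[idx])])
  }, numeric(1))
  names(out) <- objectives()
  out
}

#' @export
print.scenario <- function(x, ...) {
  w <- as_weight(x$weighting)
  cat(sprintf("Scenario w=(%g,%g,%g)%s: conversion rate %.1f%%\n",
              w[1], w[2], w[3],
              if (is.na(x$budget)) "" else sprintf(", budget %.0f%%", 100 * x$budget),
              100 * x$conversion_rate))
  p <- x$performance_raw
  cat(sprintf("  carbon %.4g t CO2-eq/yr | production %.4g GBP/yr | biodiversity %.4g\n",
              p[1], p[2], p[3]))
  invisible(x)
}
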