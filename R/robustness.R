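#' Per-cell conversion frequencies over a scenario ensemble
#'
#' How robust is a conversion to the choice of priority weighting? For every
#' cell, the share of scenarios in which it is converted (assignment differs
#' from the current use), and per target category the share of scenarios in
#' which it is converted to that category. Shares are relative to the full
#' (filtered) ensemble, so per cell the four category shares plus the
#' unchanged share sum to 1.
#'
#' @param scenarios list of `scenario` objects sharing one landscape.
#' @param group_filter `"all"` (default) or one of the priority-group labels
#'   (`"carbon"`, `"production"`, `"biodiversity"`, `"balanced"`); only
#'   scenarios whose weighting belongs to the group are counted.
#' @param current_use integer per-cell current categories (taken from the
#'   first scenario's conversion mask definition; must be supplied explicitly
#'   because scenarios store assignments, not the landscape).
#' @return an object of class `frequency_map`: `share_changed` (per cell),
#'   `share_to` (`cells x 4`), ensemble size and the group label.
#' @export
conversion_frequency <- function(scenarios, group_filter = "all", current_use) {
  if (!length(scenarios)) stop("empty ensemble", call. = FALSE)
  if (!identical(group_filter, "all")) {
    keep <- vapply(scenarios, function(s)
      group_filter %in% classify_weighting(s$weighting), logical(1))
    scenarios <- scenarios[keep]
    if (!length(scenarios)) stop("empty ensemble after group filtering", call. = FALSE)
  }
  n <- length(scenarios[[1]]$assignment)
  counts <- matrix(0, n, 4L, dimnames = list(NULL, lu_categories()))
  for (s in scenarios) {
    if (length(s$assignment) != n)
      stop("alignment error: scenarios on different grids", call. = FALSE)
    conv <- s$assignment != current_use
    for (k in 1:4) counts[, k] <- counts[, k] + (conv & s$assignment == k)
  }
  m <- length(scenarios)
  structure(list(share_changed = rowSums(counts) / m,
                 share_to = counts / m,
                 n_scenarios = m, group = group_filter),
            class = "frequency_map")
}

#' Cells with identical conversions / no conversions across an ensemble
#'
#' Splits out the cells on which the whole ensemble agrees: cells where every
#' scenario converts to the same non-current category, and cells where no
#' scenario converts. The two sets are disjoint; cells with any disagreement
#' fall in neither.
#'
#' @param scenarios non-empty list of `scenario` objects.
#' @param current_use integer per-cell current categories.
#' @return list with integer index vectors `same_conversion` and `unchanged`,
#'   plus `same_target`, the agreed category per `same_conversion` cell.
#' @export
common_conversions <- function(scenarios, current_use) {
  if (!length(scenarios)) stop("empty ensemble", call. = FALSE)
  amat <- vapply(scenarios, function(s) s$assignment,
                 integer(length(current_use)))
  amat <- matrix(amat, ncol = length(scenarios))
  first <- amat[, 1]
  all_same <- rowSums(amat != first) == 0L
  unchanged <- which(all_same & first == current_use)
  same_conv <- which(all_same & first != current_use)
  list(same_conversion = same_conv, unchanged = unchanged,
       same_target = first[same_conv])
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("Conversion-frequency map (%s group, %d scenarios)\n",
              x$group, x$n_scenarios))
  cat(sprintf("  cells ever converted: %.1f%%; converted in all scenarios: %.1f%%\n",
              100 * mean(x$share_changed > 0), 100 * mean(x$share_changed == 1)))
  invisible(x)
}

#' @param x a `frequency_map`.
#' @param landscape the landscape the ensemble was computed on (grid shape).
#' @param ... passed to [graphics::image()].
#' @rdname conversion_frequency
#' @export
plot.frequency_map <- function(x, landscape, ...) {
  m <- matrix(x$share_changed, landscape$n_rows, landscape$n_cols)
  graphics::image(t(m)[, landscape$n_rows:1], zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = sprintf("Share of scenarios converted (%s)",
                                               x$group), ...)
  invisible(x)
}
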