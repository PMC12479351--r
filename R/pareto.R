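#' Aggregate performance bounds per objective
#'
#' The minimum (maximum) aggregate performance of each objective under
#' unlimited conversion is the sum over convertible cells of the per-cell
#' minimum (maximum) across the four categories; these bounds anchor the 0-1
#' normalisation of scenario performances (0 = objective minimised, 1 =
#' objective maximised).
#'
#' @param maps a `benefit_maps` object.
#' @return 2 x 3 matrix with rows `min`, `max` and objective columns.
#' @export
compute_bounds <- function(maps) {
  stopifnot(inherits(maps, "benefit_maps"))
  idx <- which(maps$convertible)
  out <- matrix(NA_real_, 2, 3, dimnames = list(c("min", "max"), objectives()))
  for (o in 1:3) {
    layer <- maps$raw[idx, , o, drop = FALSE]
    dim(layer) <- c(length(idx), 4L)
    out["min", o] <- sum(pmin(layer[, 1], layer[, 2], layer[, 3], layer[, 4]))
    out["max", o] <- sum(pmax(layer[, 1], layer[, 2], layer[, 3], layer[, 4]))
  }
  out
}

#' Normalise a performance triple against the aggregate bounds
#'
#' @param triple named or ordered numeric vector (carbon, production,
#'   biodiversity) in raw units.
#' @param bounds result of [compute_bounds()].
#' @return numeric triple; any achievable scenario maps into [0, 1].
#' @export
normalize_performance <- function(triple, bounds) {
  triple <- as.numeric(triple)
  if (any(bounds["max", ] == bounds["min", ]))
    stop("degenerate-bounds error: an objective has max_agg == min_agg", call. = FALSE)
  out <- (triple - bounds["min", ]) / (bounds["max", ] - bounds["min", ])
  names(out) <- objectives()
  out
}

# coerce points to a numeric matrix with 3 (or n) columns
as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  storage.mode(points) <- "double"
  points
}

#' Non-dominated (Pareto-efficient) subset
#'
#' A point is dominated when some other point is at least as good in every
#' objective and strictly better in at least one (weak dominance, all
#' objectives maximised). Duplicate triples are retained once.
#'
#' @param points numeric matrix or data.frame, one row per scenario.
#' @return the non-dominated rows, with attribute `indices` giving their row
#'   numbers in the (deduplicated) input.
#' @export
pareto_filter <- function(points) {
  p <- unique(as_points(points))
  keep <- !is_dominated(p)
  structure(p[keep, , drop = FALSE], indices = which(keep))
}

#' Which points are dominated?
#'
#' @param points numeric matrix, objectives in columns, all maximised.
#' @return logical vector: `TRUE` where some other row weakly dominates.
#' @export
is_dominated <- function(points) {
  p <- as_points(points)
  n <- nrow(p)
  dom <- logical(n)
  for (i in seq_len(n)) {
    ge <- rep(TRUE, n)
    gt <- rep(FALSE, n)
    for (j in seq_len(ncol(p))) {
      ge <- ge & p[, j] >= p[i, j]
      gt <- gt | p[, j] > p[i, j]
    }
    dom[i] <- any(ge & gt)
  }
  dom
}

#' Pairwise two-objective frontier
#'
#' Projects the scenario points onto two objectives, keeps the 2D
#' non-dominated subset, and returns it sorted by the first objective
#' ascending; along the result the second objective is strictly decreasing
#' (a monotone staircase).
#'
#' @param points matrix/data.frame of normalised triples.
#' @param obj_i,obj_j column indices or names of the two objectives.
#' @return matrix with columns `(obj_i, obj_j)` and attribute `indices`
#'   (rows of the deduplicated projection kept).
#' @export
pairwise_frontier <- function(points, obj_i, obj_j) {
  p <- as_points(points)
  if (nrow(p) < 1) stop("frontier requires at least one point", call. = FALSE)
  proj <- unique(p[, c(obj_i, obj_j), drop = FALSE])
  keep <- which(!is_dominated(proj))
  keep <- keep[order(proj[keep, 1], -proj[keep, 2])]
  structure(proj[keep, , drop = FALSE], indices = keep)
}

#' Best achievable improvement of one objective with the others guarded
#'
#' Measures how far the current performance sits from the scenario cloud
#' along one axis: the maximum of the target objective over scenarios whose
#' guard objectives are all at least the current values. With both other
#' objectives as guards this is the axis-parallel distance to the frontier;
#' with a single guard it answers questions like "how much more carbon
#' without losing production?".
#'
#' @param points matrix/data.frame of normalised triples.
#' @param current normalised triple of the current state.
#' @param target_obj objective to improve (index or name).
#' @param guard_objs objectives not allowed to fall below the current values
#'   (default: both others).
#' @return list with `no_intersection` flag; when feasible, `value` (best
#'   target value), `gain` (value minus current), `witness` (row index into
#'   `points`) and `deltas` (witness minus current on all objectives).
#' @export
constrained_improvement <- function(points, current, target_obj,
                                    guard_objs = NULL) {
  p <- as_points(points)
  current <- as.numeric(current)
  cols <- seq_len(ncol(p))
  ti <- if (is.character(target_obj)) match(target_obj, colnames(p)) else target_obj
  if (is.null(guard_objs)) guard_objs <- setdiff(cols, ti)
  gi <- if (is.character(guard_objs)) match(guard_objs, colnames(p)) else guard_objs
  feasible <- rep(TRUE, nrow(p))
  for (g in gi) feasible <- feasible & p[, g] >= current[g]
  if (!any(feasible)) return(list(no_intersection = TRUE))
  vals <- p[, ti]
  vals[!feasible] <- -Inf
  witness <- which.max(vals)
  list(no_intersection = FALSE,
       value = p[witness, ti],
       gain = p[witness, ti] - current[ti],
       witness = witness,
       deltas = p[witness, ] - current)
}

#' Scenarios at least as good as the current state in all objectives
#'
#' @param points matrix/data.frame of normalised triples.
#' @param current normalised current triple.
#' @return row indices of the strictly-better set (weak inequality in every
#'   objective, so a point equal to `current` is included).
#' @export
strictly_better <- function(points, current) {
  p <- as_points(points)
  current <- as.numeric(current)
  ok <- rep(TRUE, nrow(p))
  for (j in seq_len(ncol(p))) ok <- ok & p[, j] >= current[j]
  which(ok)
}
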