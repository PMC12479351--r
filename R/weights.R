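#' Enumerate the discrete weight simplex
#'
#' All 3-way objective weightings (carbon, production, biodiversity) on the
#' percent simplex with the given step, in lexicographic order. With step 5
#' this yields the 231 weighting vectors of the full scan; in general the
#' count is `(100/step + 1) * (100/step + 2) / 2`. Weights are stored as
#' integer percents so simplex arithmetic and group membership are exact.
#'
#' @param step integer percent step; must divide 100.
#' @return data.frame with integer columns `w_C`, `w_P`, `w_B` summing to 100.
#' @export
enumerate_weights <- function(step = 5L) {
  step <- as.integer(step)
  if (step <= 0L || 100L %% step != 0L)
    stop("config error: step must be a positive divisor of 100", call. = FALSE)
  grid <- seq(0L, 100L, by = step)
  out <- do.call(rbind, lapply(grid, function(wc) {
    wp <- seq(0L, 100L - wc, by = step)
    cbind(w_C = wc, w_P = wp, w_B = 100L - wc - wp)
  }))
  as.data.frame(out)
}

#' Classify a weighting into priority groups
#'
#' A weighting is carbon / production / biodiversity prioritising when that
#' objective's weight is >= 50, and balanced when all three weights are <= 50.
#' Boundary weightings (an objective at exactly 50) belong to both the
#' objective-focused group and the balanced group; each of the four groups
#' drawn from the step-5 grid contains 66 of the 231 weightings.
#'
#' @param w integer weights: a length-3 vector `(w_C, w_P, w_B)` or a one-row
#'   data.frame from [enumerate_weights()].
#' @return character vector of group labels (at least one).
#' @export
classify_weighting <- function(w) {
  w <- as_weight(w)
  groups <- c("carbon", "production", "biodiversity")[w >= 50]
  if (all(w <= 50)) groups <- c(groups, "balanced")
  groups
}

#' Priority-group labels for a table of weightings
#'
#' @param weights data.frame from [enumerate_weights()].
#' @return character vector, labels joined by `"+"` per weighting.
#' @export
weight_groups <- function(weights) {
  vapply(seq_len(nrow(weights)), function(i)
    paste(classify_weighting(weights[i, ]), collapse = "+"), character(1))
}

# coerce the accepted weighting representations to an integer triple
as_weight <- function(w) {
  if (is.data.frame(w)) w <- unlist(w[1, c("w_C", "w_P", "w_B")])
  w <- as.numeric(w)
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 100) > 1e-9)
    stop("config error: weighting must be three non-negative percents summing to 100",
         call. = FALSE)
  w
}
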