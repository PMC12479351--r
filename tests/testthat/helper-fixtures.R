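# hand-built landscape with fully controlled fields (no generator involved)
manual_landscape <- function(nr, nc, current, subhabitat = NULL, peat = FALSE,
                             arable_yield = 500, pasture_suitability = 50,
                             pasture_revenue = 300, forest_yield_class = 12,
                             occurrence = NULL, n_species = 2, cell_area = 25,
                             convertible = TRUE, seed = 1L) {
  n <- nr * nc
  rec <- function(v) rep_len(v, n)
  current <- rec(current)
  if (is.null(subhabitat)) {
    subhabitat <- rep(NA_integer_, n)
    subhabitat[current == 4L] <- 4L  # broadleaved by default
  } else subhabitat <- rec(subhabitat)
  if (is.null(occurrence)) {
    occurrence <- array(0.5, dim = c(n, n_species, 4L),
                        dimnames = list(NULL, NULL, lu_categories()))
  }
  structure(list(
    n_rows = as.integer(nr), n_cols = as.integer(nc), cell_area = cell_area,
    config = synth_config(nr, nc, seed = seed, n_species = n_species),
    current_use = current, subhabitat = subhabitat, peat = rec(peat),
    convertible = rec(convertible), arable_yield = rec(arable_yield),
    pasture_suitability = rec(pasture_suitability),
    pasture_revenue = rec(pasture_revenue),
    forest_yield_class = rec(forest_yield_class),
    occurrence = occurrence), class = "landscape")
}

# benefit maps with a fully random raw array (for allocator/pareto oracles)
random_benefit_maps <- function(n, seed, current = NULL) {
  set.seed(seed)
  raw <- array(rnorm(n * 12), dim = c(n, 4L, 3L),
               dimnames = list(NULL, lu_categories(),
                               c("carbon", "production", "biodiversity")))
  if (is.null(current)) current <- sample.int(4L, n, replace = TRUE)
  structure(list(raw = raw, n_rows = n, n_cols = 1L, cell_area = 25,
                 current_use = current, convertible = rep(TRUE, n),
                 subhabitat = rep(NA_integer_, n), params = list()),
            class = "benefit_maps")
}

# exhaustive-search oracle: best total weighted benefit over all 4^n
# assignments with at most max_changes cells differing from current
# (max_changes = n means unconstrained)
brute_force_best <- function(bw, current, max_changes = nrow(bw)) {
  n <- nrow(bw)
  alloc <- as.matrix(expand.grid(rep(list(1:4), n)))
  total <- numeric(nrow(alloc))
  changes <- integer(nrow(alloc))
  for (cell in seq_len(n)) {
    total <- total + bw[cell, alloc[, cell]]
    changes <- changes + (alloc[, cell] != current[cell])
  }
  max(total[changes <= max_changes])
}

# total weighted benefit of a scenario under a weighting
scenario_weighted_total <- function(scenario, norm, w) {
  bw <- weighted_benefit(norm, w)
  idx <- which(norm$convertible)
  sum(bw[cbind(idx, scenario$assignment[idx])])
}

# independent O(n^2) dominance oracle (nested loops, no vectorisation shared
# with the implementation)
oracle_nondominated <- function(p) {
  n <- nrow(p)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(p[j, ] >= p[i, ]) && any(p[j, ] > p[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}
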