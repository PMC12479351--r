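#' Pipeline configuration
#'
#' Bundles the synthetic-landscape configuration, the benefit parameter sets,
#' the weight-simplex step and the conversion-budget list into one object.
#' The default budgets are 1% and then 10% steps up to 100%; a budget of 1
#' is the unlimited case and coincides with [optimal_allocation()].
#'
#' @param synth a [synth_config()].
#' @param step weight-simplex step in percent (default 5, the 231-vector scan).
#' @param budgets sorted unique fractions in [0, 1].
#' @param seed integer base seed for budget tie-breaking (scenario i uses
#'   `seed + i`).
#' @param tie_rule argmax tie rule for the allocator.
#' @param cparams,pparams,bparams benefit parameter objects.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth,
                            step = 5L,
                            budgets = c(0.01, seq(0.1, 1, by = 0.1)),
                            seed = 1L,
                            tie_rule = "current_first",
                            cparams = carbon_params(),
                            pparams = production_params(),
                            bparams = biodiversity_params()) {
  stopifnot(inherits(synth, "synth_config"))
  if (any(budgets < 0) || any(budgets > 1))
    stop("config error: budgets must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(budgets, strictly = TRUE))
    stop("config error: budgets must be sorted and unique", call. = FALSE)
  if (100L %% as.integer(step) != 0L)
    stop("config error: step must divide 100", call. = FALSE)
  structure(list(synth = synth, step = as.integer(step), budgets = budgets,
                 seed = as.integer(seed), tie_rule = tie_rule,
                 cparams = cparams, pparams = pparams, bparams = bparams),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()] and
#' [synth_config()]; anything omitted keeps its default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  y <- yaml::read_yaml(path)
  synth_args <- y[intersect(names(y), names(formals(synth_config)))]
  synth <- do.call(synth_config, synth_args)
  pipe_args <- y[intersect(names(y), c("step", "budgets", "seed", "tie_rule"))]
  do.call(pipeline_config, c(list(synth = synth), pipe_args))
}

#' Run the full reallocation analysis
#'
#' Executes the pipeline end to end: synthetic landscape, benefit maps,
#' normalisation, one scenario per (weighting, budget) pair, performance
#' normalisation against the aggregate bounds, per-budget Pareto flags,
#' the strictly-better set relative to the current land use, and per-cell
#' conversion-frequency maps (overall and per priority group) over the
#' unlimited-budget ensemble. Fully deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, scenario and frequency
#'   tables are written as CSV (headers name the units) and the landscape and
#'   benefit maps as ASCII grids.
#' @param quiet suppress stage messages.
#' @return an object of class `landalloc_run`: `scenarios` (data.frame),
#'   `scenario_objects`, `current` (raw and normalised triples), `bounds`,
#'   `frequency` (list of `frequency_map`s), `landscape`, `maps`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]

  say("stage 1/5: synthetic landscape (%d x %d)",
      config$synth$n_rows, config$synth$n_cols)
  landscape <- generate_landscape(config$synth)

  say("stage 2/5: benefit maps")
  maps <- compute_benefit_maps(landscape, config$cparams, config$pparams,
                               config$bparams)
  norm <- normalize_benefits(maps)
  bounds <- compute_bounds(maps)

  say("stage 3/5: scenarios (%d weightings x %d budgets)",
      nrow(enumerate_weights(config$step)), length(config$budgets))
  weights <- enumerate_weights(config$step)
  groups <- weight_groups(weights)
  scen <- vector("list", nrow(weights) * length(config$budgets))
  rows <- vector("list", length(scen))
  i <- 0L
  for (wi in seq_len(nrow(weights))) {
    w <- unlist(weights[wi, ])
    for (budget in config$budgets) {
      i <- i + 1L
      s <- budget_allocation(norm, w, budget, seed = config$seed + i,
                             tie_rule = config$tie_rule)
      scen[[i]] <- s
      rows[[i]] <- data.frame(
        w_C = w[1], w_P = w[2], w_B = w[3], budget = budget,
        seed = config$seed + i, groups = groups[wi],
        carbon_tCO2e_yr = s$performance_raw[["carbon"]],
        production_GBP_yr = s$performance_raw[["production"]],
        biodiversity_index = s$performance_raw[["biodiversity"]],
        conversion_rate = s$conversion_rate)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  say("stage 4/5: performance normalisation, Pareto and strictly-better sets")
  keep_scenario <- structure(list(assignment = norm$current_use), class = "scenario")
  current_raw <- evaluate_scenario(keep_scenario, maps)
  current_norm <- normalize_performance(current_raw, bounds)
  nt <- t(apply(tab[, c("carbon_tCO2e_yr", "production_GBP_yr",
                        "biodiversity_index")], 1,
                normalize_performance, bounds = bounds))
  colnames(nt) <- paste0(objectives(), "_norm")
  tab <- cbind(tab, nt)
  tab$is_pareto <- FALSE
  for (b in unique(tab$budget)) {
    sel <- tab$budget == b
    tab$is_pareto[sel] <- !is_dominated(nt[sel, , drop = FALSE])
  }
  tab$is_strictly_better <- seq_len(nrow(tab)) %in%
    strictly_better(nt, current_norm)

  say("stage 5/5: conversion-frequency maps")
  full_budget <- scen[tab$budget == max(config$budgets)]
  freq <- c(list(all = conversion_frequency(full_budget, "all",
                                            landscape$current_use)),
            stats::setNames(lapply(
              c("carbon", "production", "biodiversity", "balanced"),
              function(g) conversion_frequency(full_budget, g,
                                               landscape$current_use)),
              c("carbon", "production", "biodiversity", "balanced")))

  run <- structure(list(scenarios = tab, scenario_objects = scen,
                        current = list(raw = current_raw, norm = current_norm),
                        bounds = bounds, frequency = freq,
                        landscape = landscape, maps = maps, norm = norm,
                        config = config),
                   class = "landalloc_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  say("done in %.1f s", proc.time()[3] - t0)
  run
}

#' Write the pipeline outputs to CSV and ASCII grids
#'
#' @param run a `landalloc_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "landalloc_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$scenarios, file.path(dir, "scenarios.csv"),
                   row.names = FALSE)
  bounds <- as.data.frame(run$bounds)
  bounds <- cbind(bound = rownames(run$bounds), bounds)
  utils::write.csv(bounds, file.path(dir, "bounds.csv"), row.names = FALSE)
  cur <- data.frame(objective = objectives(),
                    raw = as.numeric(run$current$raw),
                    normalized = as.numeric(run$current$norm))
  utils::write.csv(cur, file.path(dir, "current_performance.csv"),
                   row.names = FALSE)
  for (g in names(run$frequency)) {
    f <- run$frequency[[g]]
    df <- data.frame(cell = seq_along(f$share_changed),
                     share_changed = f$share_changed, f$share_to,
                     check.names = FALSE)
    names(df)[3:6] <- paste0("share_to_", lu_categories())
    utils::write.csv(df, file.path(dir, sprintf("frequency_%s.csv", g)),
                     row.names = FALSE)
  }
  write_landscape(run$landscape, file.path(dir, "landscape"))
  write_benefit_maps(run$maps, file.path(dir, "benefits"))
  invisible(dir)
}

#' @export
print.landalloc_run <- function(x, ...) {
  cat(sprintf("Land-reallocation run: %d scenarios (%d weightings x %d budgets) on %d x %d cells\n",
              nrow(x$scenarios), nrow(enumerate_weights(x$config$step)),
              length(x$config$budgets), x$landscape$n_rows, x$landscape$n_cols))
  cat(sprintf("  current normalized performance: carbon %.3f, production %.3f, biodiversity %.3f\n",
              x$current$norm[1], x$current$norm[2], x$current$norm[3]))
  cat(sprintf("  Pareto-flagged scenarios: %d; strictly better than current: %d\n",
              sum(x$scenarios$is_pareto), sum(x$scenarios$is_strictly_better)))
  invisible(x)
}

#' @export
summary.landalloc_run <- function(object, ...) {
  tab <- object$scenarios
  full <- tab[tab$budget == max(tab$budget), ]
  nt <- as.matrix(full[, paste0(objectives(), "_norm")])
  imp <- lapply(objectives(), function(o)
    constrained_improvement(nt, object$current$norm, paste0(o, "_norm")))
  names(imp) <- objectives()
  out <- list(n_scenarios = nrow(tab),
              current = object$current,
              bounds = object$bounds,
              conversion_rate_range = range(full$conversion_rate),
              n_strictly_better = sum(full$is_strictly_better),
              axis_improvements = imp)
  class(out) <- "summary.landalloc_run"
  out
}

#' @export
print.summary.landalloc_run <- function(x, ...) {
  cat(sprintf("%d scenarios; current normalized performance (C, P, B): %.3f, %.3f, %.3f\n",
              x$n_scenarios, x$current$norm[1], x$current$norm[2], x$current$norm[3]))
  cat(sprintf("unlimited-budget conversion rates: %.1f%% to %.1f%%\n",
              100 * x$conversion_rate_range[1], 100 * x$conversion_rate_range[2]))
  cat(sprintf("strictly better than current (unlimited budget): %d scenarios\n",
              x$n_strictly_better))
  for (o in names(x$axis_improvements)) {
    im <- x$axis_improvements[[o]]
    if (isTRUE(im$no_intersection))
      cat(sprintf("  %s: no scenario improves it with the other objectives guarded\n", o))
    else
      cat(sprintf("  %s: axis-parallel gain %+.3f (normalized) over current\n",
                  o, im$gain))
  }
  invisible(x)
}

#' Pairwise Pareto panels for a pipeline run
#'
#' Plots the three two-objective projections of the scenario cloud for the
#' unlimited budget, the pairwise frontier staircase, and the current state.
#'
#' @param x a `landalloc_run`.
#' @param budget which budget's scenarios to show (default: the largest).
#' @param ... unused.
#' @export
plot.landalloc_run <- function(x, budget = max(x$scenarios$budget), ...) {
  tab <- x$scenarios[x$scenarios$budget == budget, ]
  nt <- as.matrix(tab[, paste0(objectives(), "_norm")])
  colnames(nt) <- objectives()
  pairs <- list(c(2, 1), c(2, 3), c(1, 3))
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    graphics::plot(nt[, i], nt[, j], pch = 16, cex = 0.6,
                   col = grDevices::adjustcolor("grey40", 0.6),
                   xlab = paste("normalized", objectives()[i]),
                   ylab = paste("normalized", objectives()[j]),
                   xlim = c(0, 1), ylim = c(0, 1),
                   main = sprintf("budget %.0f%%", 100 * budget))
    fr <- pairwise_frontier(nt, i, j)
    graphics::lines(fr[, 1], fr[, 2], type = "s", col = "darkorange", lwd = 2)
    graphics::points(x$current$norm[i], x$current$norm[j], pch = 8,
                     col = "red", cex = 1.4)
  }
  invisible(x)
}
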