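#' Carbon accounting parameters
#'
#' Carbon benefits combine (i) a one-off change in soil+vegetation carbon
#' stock, amortised linearly over the planning horizon, (ii) recurring annual
#' emissions attached to the target state (fertiliser N2O on arable, livestock
#' CH4/N2O on pasture), (iii) peat-state fluxes on peaty soils, and (iv) mean
#' annual forest sequestration over the horizon, with plantation sequestration
#' discounted by the share of harvested-wood carbon stored long term.
#'
#' @param stock named t C/ha soil+vegetation stocks for arable, pasture,
#'   plantation and each semi-natural sub-habitat.
#' @param fertiliser_n2o_n arable N2O-N emission, g/ha/yr (default 1460.67).
#' @param gwp_n2o 100-year global warming potential of N2O (default 273).
#' @param livestock_emissions pasture livestock emissions, t CO2-eq/ha/yr
#'   (default 7.62, an average national livestock mix applied uniformly).
#' @param peat_flux named t CO2-eq/ha/yr net flux (sequestration positive) of
#'   a peat cell under each target category; drained agricultural states emit.
#' @param wood_product_share fraction of plantation sequestration stored
#'   long-term in harvested wood products (default 0.482).
#' @param horizon planning horizon in years (default 30, i.e. 2020-2050).
#' @param growth parameters of the yield-class growth curves used for forest
#'   sequestration; see [forest_growth_rate()].
#' @return an object of class `carbon_params`.
#' @export
carbon_params <- function(stock = c(arable = 85, pasture = 105, plantation = 140,
                                    grassland = 115, heath = 125, fenbog = 300,
                                    broadleaved = 175),
                          fertiliser_n2o_n = 1460.67,
                          gwp_n2o = 273,
                          livestock_emissions = 7.62,
                          peat_flux = c(arable = -24, pasture = -18,
                                        plantation = -8, seminatural = 2),
                          wood_product_share = 0.482,
                          horizon = 30,
                          growth = list(
                            managed    = c(scale = 14, midpoint = 22, slope = 7),
                            broadleaved = c(scale = 11, midpoint = 35, slope = 10))) {
  if (any(stock < 0)) stop("configuration error: stocks must be >= 0", call. = FALSE)
  if (wood_product_share < 0 || wood_product_share > 1)
    stop("configuration error: wood_product_share must lie in [0, 1]", call. = FALSE)
  if (horizon <= 0) stop("configuration error: horizon must be > 0", call. = FALSE)
  need <- c(lu_categories()[-4], seminatural_subhabitats())
  if (!all(need %in% names(stock)))
    stop("configuration error: stock table missing classes: ",
         paste(setdiff(need, names(stock)), collapse = ", "), call. = FALSE)
  if (!all(lu_categories() %in% names(peat_flux)))
    stop("configuration error: peat_flux must cover all four categories", call. = FALSE)
  structure(list(stock = stock, fertiliser_n2o_n = fertiliser_n2o_n,
                 gwp_n2o = gwp_n2o, livestock_emissions = livestock_emissions,
                 peat_flux = peat_flux, wood_product_share = wood_product_share,
                 horizon = horizon, growth = growth),
            class = "carbon_params")
}

#' Production (revenue) parameters
#'
#' @param suitability_threshold pasture suitability index below which pasture
#'   brings no returns (default 20; "under 20" means 20 itself is productive).
#' @param timber_price GBP per tonne of harvested biomass (default 55).
#' @param carbon_density t C per t biomass of the plantation species mix
#'   (default 0.5).
#' @return an object of class `production_params`.
#' @export
production_params <- function(suitability_threshold = 20,
                              timber_price = 55,
                              carbon_density = 0.5) {
  if (suitability_threshold < 0 || suitability_threshold > 100)
    stop("configuration error: suitability_threshold must lie in [0, 100]",
         call. = FALSE)
  if (timber_price < 0 || carbon_density <= 0)
    stop("configuration error: prices and densities must be positive", call. = FALSE)
  structure(list(suitability_threshold = suitability_threshold,
                 timber_price = timber_price, carbon_density = carbon_density),
            class = "production_params")
}

#' Habitat condition scores
#'
#' Land-use specific 0-1 intactness values (effective habitat area). Existing
#' established semi-natural habitats score higher (0.38-0.70 range by type,
#' natural grassland 0.30) than newly created semi-natural habitat (0.33),
#' reflecting the time habitats need to reach ecological maturity.
#'
#' @param existing named scores applied when the target category (and, for
#'   semi-natural cells, the sub-habitat) equals the current one.
#' @param new named scores applied to newly created habitat.
#' @return an object of class `biodiversity_params`.
#' @export
biodiversity_params <- function(existing = c(arable = 0.08, pasture = 0.10,
                                             plantation = 0.23,
                                             grassland = 0.30, heath = 0.45,
                                             fenbog = 0.55, broadleaved = 0.70),
                                new = c(arable = 0.08, pasture = 0.10,
                                        plantation = 0.23, seminatural = 0.33)) {
  if (any(c(existing, new) < 0) || any(c(existing, new) > 1))
    stop("configuration error: condition scores must lie in [0, 1]", call. = FALSE)
  structure(list(existing = existing, new = new), class = "biodiversity_params")
}

#' Convert an N2O-N emission rate to CO2-equivalents
#'
#' Applies the stoichiometric N2O-N to N2O conversion (44/28) and the GWP-100
#' factor: `rate * (44/28) * gwp / 1000` kg CO2-eq/ha/yr. With the default
#' arable rate of 1460.67 g N2O-N/ha/yr and GWP 273 this gives 626.63 kg
#' CO2-eq/ha/yr.
#'
#' @param rate N2O-N emission in g/ha/yr, >= 0.
#' @param gwp GWP-100 of N2O (dimensionless).
#' @return kg CO2-eq/ha/yr.
#' @export
fertiliser_emissions <- function(rate, gwp = 273) {
  if (any(rate < 0)) stop("domain error: emission rate must be >= 0", call. = FALSE)
  rate * (44 / 28) * gwp / 1000
}

#' Mean annual forest sequestration over the horizon
#'
#' Yield-class curves are a configurable table; the default is a logistic
#' cumulative-sequestration curve whose asymptote scales with yield class:
#' cumulative CO2 at stand age t is `scale * yc * plogis((t - midpoint)/slope)`,
#' and the mean annual rate over the horizon is the increment from age 0 to
#' the horizon divided by the horizon. Uniform planting over the horizon and
#' time-to-first-harvest are collapsed into this mean rate.
#'
#' @param yield_class numeric yield-class surface values.
#' @param type `"managed"` (thinned conifer plantation) or `"broadleaved"`.
#' @param params a [carbon_params()].
#' @return t CO2-eq/ha/yr, same shape as `yield_class`.
#' @export
forest_growth_rate <- function(yield_class, type = c("managed", "broadleaved"),
                               params = carbon_params()) {
  type <- match.arg(type)
  g <- params$growth[[type]]
  if (is.null(g)) stop("configuration error: unknown growth curve type", call. = FALSE)
  a <- g[["scale"]] * yield_class
  h <- params$horizon
  a * (stats::plogis((h - g[["midpoint"]]) / g[["slope"]]) -
         stats::plogis(-g[["midpoint"]] / g[["slope"]])) / h
}

#' Assign the future semi-natural sub-habitat of every cell
#'
#' If a cell were restored to semi-natural habitat, which sub-habitat would it
#' become? Every convertible cell receives the sub-habitat of its nearest
#' existing semi-natural cell (Euclidean distance between cell centres, first
#' donor in column-major order on ties), except that peaty-soil cells are
#' always assigned fen/bog regardless of the nearest donor, and existing
#' semi-natural cells keep their own sub-type. If the landscape has no
#' semi-natural cell, peat cells (forced to fen/bog) act as donors; with
#' neither donors nor peat the assignment is undefined.
#'
#' @param landscape a [generate_landscape()] result.
#' @return integer vector over cells indexing [seminatural_subhabitats()].
#' @export
assign_future_habitat <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  n <- landscape$n_rows * landscape$n_cols
  subs <- seminatural_subhabitats()
  fen <- match("fenbog", subs)
  donors <- which(landscape$current_use == 4L)
  donor_sub <- landscape$subhabitat[donors]
  if (!length(donors)) {
    if (!any(landscape$peat))
      stop("assignment error: no semi-natural donor habitat and no peat", call. = FALSE)
    donors <- which(landscape$peat)
    donor_sub <- rep(fen, length(donors))
  }
  rows <- ((seq_len(n) - 1L) %% landscape$n_rows) + 1L
  cols <- ((seq_len(n) - 1L) %/% landscape$n_rows) + 1L
  out <- integer(n)
  block <- max(1L, 2e6 %/% length(donors))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rows[idx], rows[donors], "-")^2 +
      outer(cols[idx], cols[donors], "-")^2
    out[idx] <- donor_sub[max.col(-d2, ties.method = "first")]
  }
  out[landscape$peat] <- fen
  keep <- landscape$current_use == 4L
  out[keep] <- landscape$subhabitat[keep]
  out
}

#' Replace extreme outliers by their neighbourhood mean
#'
#' Cells outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are replaced by the mean of
#' their finite, non-outlier 8-neighbours (Moore ring; boundary cells use the
#' neighbours that exist). Replacements are computed from the original values,
#' so one replacement never feeds another. A constant surface has zero IQR and
#' no cell is flagged. A flagged cell with no valid neighbour falls back to
#' the mean of all valid cells.
#'
#' @param x numeric matrix with at least 9 cells; non-finite entries are left
#'   untouched and excluded from quartiles and neighbour means.
#' @return matrix of the same shape.
#' @export
smooth_outliers <- function(x) {
  stopifnot(is.matrix(x))
  if (length(x) < 9) stop("smoothing error: surface must have >= 9 cells", call. = FALSE)
  v <- as.vector(x)
  finite <- is.finite(v)
  if (!any(finite)) stop("smoothing error: no finite cells", call. = FALSE)
  q <- stats::quantile(v[finite], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out <- finite & (v < lo | v > hi)
  if (!any(out)) return(x)
  valid <- finite & !out
  if (!any(valid)) stop("smoothing error: all cells are outliers", call. = FALSE)
  nr <- nrow(x); ncl <- ncol(x)
  res <- x
  global_mean <- mean(v[valid])
  for (cell in which(out)) {
    r <- ((cell - 1L) %% nr) + 1L
    cc <- ((cell - 1L) %/% nr) + 1L
    nb_r <- pmax(1L, r - 1L):pmin(nr, r + 1L)
    nb_c <- pmax(1L, cc - 1L):pmin(ncl, cc + 1L)
    nb <- as.vector(outer(nb_r, nb_c, function(i, j) (j - 1L) * nr + i))
    nb <- setdiff(nb, cell)
    nb <- nb[valid[nb]]
    res[cell] <- if (length(nb)) mean(v[nb]) else global_mean
  }
  res
}

#' Carbon layer of the benefit maps
#'
#' For every cell and target category: the annualised stock change
#' `(stock_target - stock_current) * 44/12 / horizon * cell_area`
#' (t CO2-eq/yr; zero for keeping the current class), plus recurring terms:
#' minus fertiliser emissions for arable targets, minus livestock emissions
#' for pasture targets, the peat-state flux on peaty cells, and mean annual
#' forest sequestration for plantation (times the wood-product share) and
#' broadleaved semi-natural targets (no share).
#'
#' @param landscape a landscape.
#' @param params a [carbon_params()].
#' @param habitat_assignment result of [assign_future_habitat()].
#' @return numeric matrix `cells x 4`, t CO2-eq/yr per cell.
#' @export
carbon_benefit <- function(landscape, params = carbon_params(),
                           habitat_assignment = assign_future_habitat(landscape)) {
  stopifnot(inherits(landscape, "landscape"), inherits(params, "carbon_params"))
  n <- landscape$n_rows * landscape$n_cols
  cats <- lu_categories(); subs <- seminatural_subhabitats()
  area <- landscape$cell_area
  stock <- params$stock

  cur_key <- cats[landscape$current_use]
  sn <- landscape$current_use == 4L
  cur_key[sn] <- subs[landscape$subhabitat[sn]]
  bad <- !(cur_key %in% names(stock))
  if (any(bad))
    stop("configuration error: stock missing for class ", cur_key[which(bad)[1]],
         call. = FALSE)
  stock_cur <- stock[cur_key]

  out <- matrix(0, n, 4L, dimnames = list(NULL, cats))
  fert_t <- fertiliser_emissions(params$fertiliser_n2o_n, params$gwp_n2o) / 1000
  rate_managed <- forest_growth_rate(landscape$forest_yield_class, "managed", params)
  rate_broad <- forest_growth_rate(landscape$forest_yield_class, "broadleaved", params)

  for (k in seq_along(cats)) {
    tgt_key <- if (k == 4L) subs[habitat_assignment] else rep(cats[k], n)
    stock_tgt <- stock[tgt_key]
    delta <- (stock_tgt - stock_cur) * (44 / 12) / params$horizon * area
    delta[landscape$current_use == k] <- 0   # identity conversion: no stock change
    recur <- numeric(n)
    if (cats[k] == "arable")  recur <- recur - fert_t * area
    if (cats[k] == "pasture") recur <- recur - params$livestock_emissions * area
    if (cats[k] == "plantation")
      recur <- recur + rate_managed * params$wood_product_share * area
    if (k == 4L) {
      broad <- subs[habitat_assignment] == "broadleaved"
      recur[broad] <- recur[broad] + rate_broad[broad] * area
    }
    recur[landscape$peat] <- recur[landscape$peat] +
      params$peat_flux[[cats[k]]] * area
    out[, k] <- delta + recur
  }
  out
}

#' Production layer of the benefit maps
#'
#' Arable revenue is the outlier-smoothed crop revenue surface times cell
#' area; pasture revenue is the livestock revenue surface times area, zeroed
#' where the suitability index is under the threshold; plantation revenue is
#' mean annual harvested biomass (growth rate / (44/12) / carbon density)
#' times the timber price and area; semi-natural habitat yields no production.
#'
#' @param landscape a landscape.
#' @param params a [production_params()].
#' @param cparams carbon parameters supplying the forest growth curves.
#' @return numeric matrix `cells x 4`, GBP/yr per cell, all values >= 0.
#' @export
production_benefit <- function(landscape, params = production_params(),
                               cparams = carbon_params()) {
  stopifnot(inherits(landscape, "landscape"), inherits(params, "production_params"))
  n <- landscape$n_rows * landscape$n_cols
  if (is.null(landscape$pasture_suitability))
    stop("input error: pasture suitability surface missing", call. = FALSE)
  area <- landscape$cell_area
  cats <- lu_categories()
  out <- matrix(0, n, 4L, dimnames = list(NULL, cats))

  arable <- smooth_outliers(as_grid(landscape, landscape$arable_yield))
  out[, "arable"] <- as.vector(arable) * area

  pasture <- landscape$pasture_revenue * area
  pasture[landscape$pasture_suitability < params$suitability_threshold] <- 0
  out[, "pasture"] <- pasture

  rate <- forest_growth_rate(landscape$forest_yield_class, "managed", cparams)
  biomass <- rate / (44 / 12) / params$carbon_density    # t biomass/ha/yr
  out[, "plantation"] <- biomass * params$timber_price * area

  out
}

#' Biodiversity layer of the benefit maps
#'
#' Species occurrence probabilities are summed over species per cell and
#' target category, min-max normalised globally over all cells and the four
#' categories, and combined with the habitat condition score by geometric
#' mean: `sqrt(S_norm * condition)`. The "existing" condition applies when the
#' target equals the current category (for semi-natural targets, when the cell
#' already is semi-natural, scored by its own sub-type); otherwise the "newly
#' created" score applies.
#'
#' @param landscape a landscape with occurrence surfaces.
#' @param params a [biodiversity_params()].
#' @param habitat_assignment result of [assign_future_habitat()] (unused for
#'   scoring new habitat, whose condition is a single "new" value, but kept in
#'   the signature for provenance symmetry).
#' @return numeric matrix `cells x 4` with values in [0, 1].
#' @export
biodiversity_benefit <- function(landscape, params = biodiversity_params(),
                                 habitat_assignment = assign_future_habitat(landscape)) {
  stopifnot(inherits(landscape, "landscape"), inherits(params, "biodiversity_params"))
  n <- landscape$n_rows * landscape$n_cols
  cats <- lu_categories(); subs <- seminatural_subhabitats()
  s <- apply(landscape$occurrence, c(1, 3), sum)   # cells x 4 occurrence sum
  rng <- range(s)
  s_norm <- if (rng[1] == rng[2]) {
    warning("occurrence indicator is constant; normalised to 0")
    matrix(0, n, 4L)
  } else (s - rng[1]) / (rng[2] - rng[1])

  cond <- matrix(NA_real_, n, 4L, dimnames = list(NULL, cats))
  for (k in seq_along(cats)) {
    if (k < 4L) {
      key <- cats[k]
      if (!key %in% names(params$new) || !key %in% names(params$existing))
        stop("configuration error: condition missing for ", key, call. = FALSE)
      cond[, k] <- ifelse(landscape$current_use == k,
                          params$existing[[key]], params$new[[key]])
    } else {
      cond[, k] <- params$new[["seminatural"]]
      sn <- which(landscape$current_use == 4L)
      key <- subs[landscape$subhabitat[sn]]
      if (!all(key %in% names(params$existing)))
        stop("configuration error: condition missing for a sub-habitat", call. = FALSE)
      cond[sn, k] <- params$existing[key]
    }
  }
  sqrt(s_norm * cond)
}

#' Assemble the twelve benefit maps
#'
#' Combines the three objective layers (each `cells x 4` categories) into one
#' container: the raw benefit of converting each cell to each category, for
#' carbon (t CO2-eq/yr), production (GBP/yr) and biodiversity (unitless, 0-1),
#' together with grid geometry, the current land use, the convertibility mask
#' and a parameter snapshot for provenance.
#'
#' @param carbon,production,biodiversity `cells x 4` matrices on one grid.
#' @param landscape the common landscape.
#' @param params optional named list of parameter objects recorded verbatim.
#' @return an object of class `benefit_maps` with field `raw`, an array
#'   `cells x 4 categories x 3 objectives`.
#' @export
assemble_benefit_maps <- function(carbon, production, biodiversity, landscape,
                                  params = list()) {
  dims <- vapply(list(carbon, production, biodiversity), function(m)
    paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    stop("alignment error: benefit layers have mismatched shapes", call. = FALSE)
  n <- landscape$n_rows * landscape$n_cols
  if (nrow(carbon) != n)
    stop("alignment error: layers do not match the landscape grid", call. = FALSE)
  raw <- array(NA_real_, dim = c(n, 4L, 3L),
               dimnames = list(NULL, lu_categories(), objectives()))
  raw[, , 1] <- carbon; raw[, , 2] <- production; raw[, , 3] <- biodiversity
  structure(list(raw = raw, n_rows = landscape$n_rows, n_cols = landscape$n_cols,
                 cell_area = landscape$cell_area,
                 current_use = landscape$current_use,
                 convertible = landscape$convertible,
                 subhabitat = landscape$subhabitat,
                 params = params),
            class = "benefit_maps")
}

#' Compute all benefit maps for a landscape
#'
#' Convenience wrapper running habitat assignment and the three objective
#' layers with the supplied (default) parameter sets.
#'
#' @param landscape a landscape.
#' @param cparams,pparams,bparams parameter objects.
#' @return a `benefit_maps` object.
#' @export
compute_benefit_maps <- function(landscape,
                                 cparams = carbon_params(),
                                 pparams = production_params(),
                                 bparams = biodiversity_params()) {
  hab <- assign_future_habitat(landscape)
  assemble_benefit_maps(
    carbon = carbon_benefit(landscape, cparams, hab),
    production = production_benefit(landscape, pparams, cparams),
    biodiversity = biodiversity_benefit(landscape, bparams, hab),
    landscape = landscape,
    params = list(carbon = cparams, production = pparams, biodiversity = bparams,
                  habitat_assignment = hab))
}

#' @export
print.benefit_maps <- function(x, ...) {
  cat(sprintf("Benefit maps: %d cells x 4 categories x 3 objectives\n",
              dim(x$raw)[1]))
  for (o in objectives()) {
    r <- range(x$raw[, , o])
    cat(sprintf("  %-12s [%.4g, %.4g]\n", o, r[1], r[2]))
  }
  invisible(x)
}
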