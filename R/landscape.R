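#' Land-use categories used throughout the package
#'
#' Every grid cell is currently one of, and can be converted to any of, four
#' broad rural land-use categories: arable land, (improved) pasture,
#' plantation (conifer) forest, and semi-natural habitat. Semi-natural cells
#' additionally carry a sub-habitat (natural grassland, heath, fen/bog, or
#' broadleaved woodland) because carbon stocks and habitat condition differ
#' strongly between them.
#'
#' @format `lu_categories()` returns a character vector of length 4;
#'   `seminatural_subhabitats()` a character vector of length 4.
#' @export
lu_categories <- function() c("arable", "pasture", "plantation", "seminatural")

#' @rdname lu_categories
#' @export
seminatural_subhabitats <- function() c("grassland", "heath", "fenbog", "broadleaved")

# objective names, fixed order used in all arrays
objectives <- function() c("carbon", "production", "biodiversity")

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators do not perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Gaussian smoothing of a matrix field
#'
#' Spatial autocorrelation in the synthetic landscape is produced by smoothing
#' white noise with a Gaussian kernel whose standard deviation (in cells) is
#' the configured correlation length. Edge cells use a renormalised kernel.
#'
#' @param x numeric matrix.
#' @param sigma kernel standard deviation in cells; `sigma <= 0` returns `x`.
#' @return smoothed matrix of the same shape.
#' @export
smooth_field <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(sigma), length(sigma) == 1L)
  if (sigma <= 0) return(x)
  smat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- exp(-0.5 * (d / sigma)^2)
    w[d > ceiling(4 * sigma)] <- 0
    w / rowSums(w)
  }
  sr <- smat(nrow(x))
  sc <- smat(ncol(x))
  sr %*% x %*% t(sc)
}

# rescale a field to [0, 1]; constant field maps to 0.5
scale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(array(0.5, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Configuration for the synthetic landscape generator
#'
#' The generator stands in for the national input stack the analysis was
#' designed around: a 500 m categorical land-cover raster (default class
#' shares 25.77% arable, 31.59% pasture, 6.49% plantation, 36.15%
#' semi-natural), continuous yield/suitability/revenue surfaces, a peat-soil
#' mask biased towards semi-natural cover, and per-species occurrence
#' probability surfaces that respond to the land-cover category.
#'
#' @param n_rows,n_cols grid dimensions (cells), both >= 1.
#' @param seed integer seed; the whole landscape is a deterministic function
#'   of the configuration.
#' @param cell_area cell area in hectares (default 25 ha, a 500 m x 500 m cell).
#' @param class_shares named fractions over [lu_categories()] summing to 1.
#' @param correlation_length Gaussian kernel sd in cells controlling spatial
#'   autocorrelation of all generated fields.
#' @param peat_fraction fraction of cells carrying peaty soil.
#' @param peat_bias additive bias making peat co-locate with semi-natural
#'   cover (in sd units of the smoothed placement field).
#' @param n_species number of species occurrence surfaces, >= 1.
#' @param affinity optional `n_species x 4` matrix (or length-4 vector recycled
#'   across species) of per-category occurrence multipliers; the default gives
#'   semi-natural habitat the highest mean occurrence probability.
#' @param subhabitat_shares fractions of non-peat semi-natural cells assigned
#'   to grassland, heath and broadleaved woodland (fen/bog is peat-driven).
#' @param outlier_rate fraction of arable-revenue cells inflated to extreme
#'   values, exercising the interquartile-range outlier filter downstream.
#' @param exclude_fraction fraction of cells marked non-convertible (stands in
#'   for water/urban/rock exclusions; exclusion is a mask, not a model).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_rows, n_cols, seed = 1L,
                         cell_area = 25,
                         class_shares = c(arable = 0.2577, pasture = 0.3159,
                                          plantation = 0.0649, seminatural = 0.3615),
                         correlation_length = 3,
                         peat_fraction = 0.10,
                         peat_bias = 1.5,
                         n_species = 8L,
                         affinity = NULL,
                         subhabitat_shares = c(grassland = 0.35, heath = 0.20,
                                               broadleaved = 0.45),
                         outlier_rate = 0.002,
                         exclude_fraction = 0) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop("dimension error: n_rows and n_cols must be >= 1", call. = FALSE)
  if (n_species < 1)
    stop("config error: n_species must be >= 1", call. = FALSE)
  cats <- lu_categories()
  if (is.null(names(class_shares)) || !setequal(names(class_shares), cats))
    stop("config error: class_shares must be named over the four categories",
         call. = FALSE)
  class_shares <- class_shares[cats]
  if (any(class_shares < 0) || any(class_shares > 1))
    stop("config error: class shares must lie in [0, 1]", call. = FALSE)
  if (abs(sum(class_shares) - 1) > 1e-9)
    stop("config error: class_shares must sum to 1", call. = FALSE)
  if (peat_fraction < 0 || peat_fraction > 1 ||
      exclude_fraction < 0 || exclude_fraction > 1)
    stop("config error: fractions must lie in [0, 1]", call. = FALSE)
  if (!is.null(affinity)) {
    if (is.vector(affinity) && length(affinity) == 4L)
      affinity <- matrix(affinity, nrow = n_species, ncol = 4L, byrow = TRUE)
    if (!is.matrix(affinity) || nrow(affinity) != n_species || ncol(affinity) != 4L)
      stop("config error: affinity must be n_species x 4", call. = FALSE)
    colnames(affinity) <- cats
  }
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    seed = as.integer(seed), cell_area = cell_area,
    class_shares = class_shares, correlation_length = correlation_length,
    peat_fraction = peat_fraction, peat_bias = peat_bias,
    n_species = as.integer(n_species), affinity = affinity,
    subhabitat_shares = subhabitat_shares,
    outlier_rate = outlier_rate, exclude_fraction = exclude_fraction
  ), class = "synth_config")
}

#' Generate a seeded synthetic landscape
#'
#' Land-cover classes are drawn by rank-thresholding a spatially smoothed
#' Gaussian field at the requested share quantiles, so realized class shares
#' match `class_shares` up to integer rounding. Peaty soil is drawn from a
#' second smoothed field with an additive bias on cells in the semi-natural
#' band, so peat preferentially co-locates with semi-natural cover.
#' Continuous surfaces (arable revenue, pasture suitability and revenue,
#' forest yield class) are further smoothed fields rescaled to realistic
#' magnitudes; species occurrence surfaces are produced by
#' [generate_occurrence_surfaces()].
#'
#' @param config a [synth_config()].
#' @return an object of class `landscape`: grid dimensions, per-cell current
#'   category and semi-natural sub-habitat, convertibility mask, attribute
#'   surfaces, peat mask, occurrence array `cells x species x category`, and
#'   the generating configuration. Cells are indexed column-major.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$n_rows; nc <- config$n_cols; n <- nr * nc
  cats <- lu_categories(); subs <- seminatural_subhabitats()

  ls <- with_seed(config$seed, {
    f_lc   <- smooth_field(matrix(stats::rnorm(n), nr, nc), config$correlation_length)
    f_peat <- smooth_field(matrix(stats::rnorm(n), nr, nc), config$correlation_length)
    f_sub  <- smooth_field(matrix(stats::rnorm(n), nr, nc), config$correlation_length)
    f_ar   <- smooth_field(matrix(stats::rnorm(n), nr, nc), config$correlation_length)
    f_pa   <- smooth_field(matrix(stats::rnorm(n), nr, nc), config$correlation_length)
    f_fo   <- smooth_field(matrix(stats::rnorm(n), nr, nc), config$correlation_length)

    # categories by field rank: counts from cumulative rounded shares are exact
    cum <- round(cumsum(config$class_shares) * n)
    cum[length(cum)] <- n
    counts <- diff(c(0L, cum))
    current <- integer(n)
    current[order(as.vector(f_lc))] <- rep.int(seq_along(cats), counts)

    # peat: second field, biased into the semi-natural band
    n_peat <- round(config$peat_fraction * n)
    score <- as.vector(scale01(f_peat)) + config$peat_bias * (current == 4L)
    peat <- logical(n)
    if (n_peat > 0)
      peat[order(score, decreasing = TRUE)[seq_len(n_peat)]] <- TRUE

    # semi-natural sub-habitats: peat -> fen/bog, rest split by a third field
    subhab <- rep(NA_integer_, n)
    sn <- which(current == 4L)
    subhab[sn[peat[sn]]] <- match("fenbog", subs)
    rest <- sn[!peat[sn]]
    if (length(rest)) {
      sh <- config$subhabitat_shares / sum(config$subhabitat_shares)
      cum2 <- round(cumsum(sh) * length(rest))
      cum2[length(cum2)] <- length(rest)
      lab <- match(names(sh), subs)
      subhab[rest[order(as.vector(f_sub)[rest])]] <-
        rep.int(lab, diff(c(0L, cum2)))
    }

    # attribute surfaces at realistic magnitudes (GB-like 2020 levels)
    arable_yield <- 400 + 500 * as.vector(scale01(f_ar))       # GBP/ha/yr
    n_out <- round(config$outlier_rate * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      arable_yield[idx] <- arable_yield[idx] * 8               # extreme outliers
    }
    pasture_suitability <- 100 * as.vector(scale01(f_pa))      # index 0-100
    pasture_revenue <- 250 + 350 * as.vector(scale01(
      0.8 * f_pa + 0.2 * matrix(stats::rnorm(n), nr, nc)))     # GBP/ha/yr
    forest_yield_class <- 4 + 20 * as.vector(scale01(f_fo))    # YC 4-24

    convertible <- rep(TRUE, n)
    n_ex <- round(config$exclude_fraction * n)
    if (n_ex > 0) convertible[sample.int(n, n_ex)] <- FALSE

    list(current_use = current, subhabitat = subhab, peat = peat,
         convertible = convertible, arable_yield = arable_yield,
         pasture_suitability = pasture_suitability,
         pasture_revenue = pasture_revenue,
         forest_yield_class = forest_yield_class)
  })

  out <- structure(c(list(n_rows = nr, n_cols = nc, cell_area = config$cell_area,
                          config = config), ls, list(occurrence = NULL)),
                   class = "landscape")
  out$occurrence <- generate_occurrence_surfaces(config, out)
  out
}

#' Generate per-species, per-category occurrence probability surfaces
#'
#' For each species a smooth spatial field in [0, 1] is modulated by a
#' per-species category affinity and clipped to [0, 1]. With the default
#' affinities, semi-natural categories receive systematically higher mean
#' occurrence probabilities, emulating species-distribution-model projections
#' re-run under altered land cover with climate held constant.
#'
#' @param config a [synth_config()].
#' @param landscape the landscape the surfaces belong to (grid shape source).
#' @return numeric array `n_cells x n_species x 4` with values in [0, 1].
#' @export
generate_occurrence_surfaces <- function(config, landscape) {
  stopifnot(inherits(config, "synth_config"), inherits(landscape, "landscape"))
  if (config$n_species < 1) stop("config error: n_species must be >= 1", call. = FALSE)
  nr <- landscape$n_rows; nc <- landscape$n_cols; n <- nr * nc
  cats <- lu_categories()
  occ_seed <- (config$seed + 1000003L) %% .Machine$integer.max
  with_seed(occ_seed, {
    aff <- config$affinity
    if (is.null(aff)) {
      base <- c(arable = 0.25, pasture = 0.35, plantation = 0.55, seminatural = 0.85)
      mult <- stats::runif(config$n_species, 0.7, 1.1)
      aff <- outer(mult, base)
      colnames(aff) <- cats
    }
    occ <- array(NA_real_, dim = c(n, config$n_species, 4L),
                 dimnames = list(NULL, NULL, cats))
    for (s in seq_len(config$n_species)) {
      f <- scale01(smooth_field(matrix(stats::rnorm(n), nr, nc),
                                config$correlation_length))
      for (k in seq_along(cats))
        occ[, s, k] <- pmin(1, pmax(0, as.vector(f) * aff[s, k]))
    }
    occ
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Synthetic landscape: %d x %d cells (%.0f ha each), seed %d\n",
              x$n_rows, x$n_cols, x$cell_area, x$config$seed))
  sh <- prop.table(tabulate(x$current_use, 4L))
  cat("  realized class shares:",
      paste(sprintf("%s %.3f", lu_categories(), sh), collapse = ", "), "\n")
  cat(sprintf("  peat: %.1f%% of cells; convertible: %.1f%%; species: %d\n",
              100 * mean(x$peat), 100 * mean(x$convertible),
              dim(x$occurrence)[2]))
  invisible(x)
}

# convert a per-cell vector to the grid matrix (column-major indexing)
as_grid <- function(landscape, v) matrix(v, landscape$n_rows, landscape$n_cols)
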