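#' Write / read a single-band raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by one row of values per grid
#' row, top row first. Values are written with 17 significant digits so
#' doubles round-trip bitwise. The nominal cell size is 500 m.
#'
#' @param x numeric matrix (rows = grid rows).
#' @param path output file path.
#' @param cellsize nominal cell size in map units (default 500).
#' @param nodata value standing in for `NA` (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cellsize = 500, nodata = -9999) {
  stopifnot(is.matrix(x))
  v <- x
  v[is.na(v)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", format(cellsize)),
    sprintf("NODATA_value %s", format(nodata)))
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  key <- vapply(hdr, `[`, character(1), 1)
  val <- vapply(hdr, `[`, character(1), 2)
  ncols <- as.integer(val[match("ncols", key)])
  nrows <- as.integer(val[match("nrows", key)])
  nodata <- as.numeric(val[match("NODATA_value", key)])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nrows * ncols)
    stop("alignment error: grid body does not match the declared shape", call. = FALSE)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  m
}

#' Write / read an integer-coded categorical raster with a CSV legend
#'
#' The grid is written as an ASCII grid of integer codes and a sidecar
#' `<path>.legend.csv` mapping codes to labels. Reading without the legend is
#' an explicit error: codes alone are not a categorical raster.
#'
#' @param x integer matrix of category codes.
#' @param path output file path for the grid.
#' @param legend data.frame with columns `code` and `label`.
#' @return `path`, invisibly.
#' @export
write_category_grid <- function(x, path, legend) {
  stopifnot(is.matrix(x), is.data.frame(legend),
            all(c("code", "label") %in% names(legend)))
  write_ascii_grid(x, path)
  utils::write.csv(legend, paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_category_grid
#' @export
read_category_grid <- function(path) {
  legend_path <- paste0(path, ".legend.csv")
  if (!file.exists(legend_path))
    stop("legend missing for categorical raster: ", legend_path, call. = FALSE)
  m <- read_ascii_grid(path)
  legend <- utils::read.csv(legend_path)
  storage.mode(m) <- "integer"
  structure(m, legend = legend)
}

#' Persist / load benefit maps as a 12-grid stack
#'
#' Writes one ASCII grid per (category, objective) pair, the current-use grid
#' with its legend, the convertibility mask, and a CSV parameter snapshot, to
#' a directory; `read_benefit_maps()` restores a `benefit_maps` object with
#' bitwise-identical values.
#'
#' @param maps a `benefit_maps` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benefit_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "benefit_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nr <- maps$n_rows; nc <- maps$n_cols
  for (k in seq_along(lu_categories()))
    for (o in seq_along(objectives()))
      write_ascii_grid(matrix(maps$raw[, k, o], nr, nc),
                       file.path(dir, sprintf("benefit_%s_%s.asc",
                                              lu_categories()[k], objectives()[o])))
  write_category_grid(matrix(maps$current_use, nr, nc),
                      file.path(dir, "current_use.asc"),
                      data.frame(code = seq_along(lu_categories()),
                                 label = lu_categories()))
  write_ascii_grid(matrix(as.numeric(maps$convertible), nr, nc),
                   file.path(dir, "convertible.asc"))
  sub <- maps$subhabitat
  sub[is.na(sub)] <- 0L
  write_category_grid(matrix(sub, nr, nc), file.path(dir, "subhabitat.asc"),
                      data.frame(code = c(0L, seq_along(seminatural_subhabitats())),
                                 label = c("none", seminatural_subhabitats())))
  snapshot <- data.frame(key = c("n_rows", "n_cols", "cell_area_ha"),
                         value = c(nr, nc, maps$cell_area))
  utils::write.csv(snapshot, file.path(dir, "parameters.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_benefit_maps
#' @export
read_benefit_maps <- function(dir) {
  snap <- utils::read.csv(file.path(dir, "parameters.csv"))
  nr <- as.integer(snap$value[snap$key == "n_rows"])
  nc <- as.integer(snap$value[snap$key == "n_cols"])
  n <- nr * nc
  raw <- array(NA_real_, dim = c(n, 4L, 3L),
               dimnames = list(NULL, lu_categories(), objectives()))
  for (k in seq_along(lu_categories()))
    for (o in seq_along(objectives())) {
      m <- read_ascii_grid(file.path(dir, sprintf("benefit_%s_%s.asc",
                                                  lu_categories()[k], objectives()[o])))
      if (nrow(m) != nr || ncol(m) != nc)
        stop("alignment error: mixed shapes in benefit-map stack", call. = FALSE)
      raw[, k, o] <- as.vector(m)
    }
  cur <- read_category_grid(file.path(dir, "current_use.asc"))
  conv <- read_ascii_grid(file.path(dir, "convertible.asc"))
  sub <- as.vector(read_category_grid(file.path(dir, "subhabitat.asc")))
  sub[sub == 0L] <- NA_integer_
  structure(list(raw = raw, n_rows = nr, n_cols = nc,
                 cell_area = snap$value[snap$key == "cell_area_ha"],
                 current_use = as.vector(unclass(cur)),
                 convertible = as.vector(conv) != 0,
                 subhabitat = sub, params = list()),
            class = "benefit_maps")
}

#' Write the landscape surfaces to a directory of ASCII grids
#'
#' @param landscape a `landscape`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- function(v) as_grid(landscape, v)
  write_category_grid(g(landscape$current_use), file.path(dir, "current_use.asc"),
                      data.frame(code = seq_along(lu_categories()),
                                 label = lu_categories()))
  write_ascii_grid(g(landscape$arable_yield), file.path(dir, "arable_yield.asc"))
  write_ascii_grid(g(landscape$pasture_suitability),
                   file.path(dir, "pasture_suitability.asc"))
  write_ascii_grid(g(landscape$pasture_revenue), file.path(dir, "pasture_revenue.asc"))
  write_ascii_grid(g(landscape$forest_yield_class),
                   file.path(dir, "forest_yield_class.asc"))
  write_ascii_grid(g(as.numeric(landscape$peat)), file.path(dir, "peat.asc"))
  write_ascii_grid(g(as.numeric(landscape$convertible)),
                   file.path(dir, "convertible.asc"))
  invisible(dir)
}
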