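test_that("fertiliser emission conversion applies 44/28 and GWP-100", {
  expect_equal(fertiliser_emissions(1460.67, 273), 626.63, tolerance = 0.01 / 626.63)
  expect_equal(fertiliser_emissions(0, 273), 0)
  # hand computation of the stoichiometric factor: 28 g N2O-N -> 44 g N2O
  expect_equal(fertiliser_emissions(28, 273), 44 * 273 / 1000)
  expect_error(fertiliser_emissions(-1), "domain error")
})

test_that("future habitat assignment uses the nearest donor with peat priority", {
  # single broadleaved donor, no peat: everything becomes broadleaved
  cur <- rep(1L, 9); cur[5] <- 4L
  ls1 <- manual_landscape(3, 3, cur, subhabitat = {
    s <- rep(NA_integer_, 9); s[5] <- 4L; s
  })
  expect_equal(assign_future_habitat(ls1), rep(4L, 9))

  # a peat cell adjacent to the broadleaved donor is assigned fen/bog anyway
  peat <- rep(FALSE, 9); peat[4] <- TRUE
  ls2 <- manual_landscape(3, 3, cur, subhabitat = {
    s <- rep(NA_integer_, 9); s[5] <- 4L; s
  }, peat = peat)
  hab <- assign_future_habitat(ls2)
  expect_equal(hab[4], match("fenbog", seminatural_subhabitats()))
  expect_equal(hab[5], 4L)

  # no donors and no peat is an error
  expect_error(assign_future_habitat(manual_landscape(2, 2, 1L)),
               "assignment error")
})

test_that("nearest-donor assignment matches a brute-force distance scan", {
  # two donors with different sub-habitats at opposite corners of a 5x5 grid
  cur <- rep(2L, 25); cur[c(1, 25)] <- 4L
  sub <- rep(NA_integer_, 25); sub[1] <- 1L; sub[25] <- 4L
  ls1 <- manual_landscape(5, 5, cur, subhabitat = sub)
  hab <- assign_future_habitat(ls1)
  rows <- ((1:25 - 1) %% 5) + 1; cols <- ((1:25 - 1) %/% 5) + 1
  for (i in 1:25) {
    d <- (rows[i] - rows[c(1, 25)])^2 + (cols[i] - cols[c(1, 25)])^2
    expect_equal(hab[i], sub[c(1, 25)][which.min(d)])
  }
})

test_that("carbon benefit has zero stock delta for identity conversions and the paper's recurring terms", {
  ls1 <- manual_landscape(3, 3, 1L)   # all arable, no peat
  cp <- carbon_params()
  hab <- rep(4L, 9)
  cb <- carbon_benefit(ls1, cp, hab)
  # arable -> arable: no stock change, only the fertiliser term on 25 ha
  expect_equal(cb[, "arable"], rep(-0.62663 * 25, 9), tolerance = 1e-5)
  # pasture target carries the livestock term -7.62 t/ha/yr on 25 ha
  delta_p <- (cp$stock[["pasture"]] - cp$stock[["arable"]]) * (44 / 12) / 30 * 25
  expect_equal(cb[, "pasture"], rep(delta_p - 7.62 * 25, 9))
  # a cell already under pasture keeps the recurring term but no stock delta
  ls2 <- manual_landscape(3, 3, 2L)
  cb2 <- carbon_benefit(ls2, cp, hab)
  expect_equal(cb2[, "pasture"], rep(-7.62 * 25, 9))
})

test_that("stock-change component is antisymmetric between category pairs", {
  cp <- carbon_params(fertiliser_n2o_n = 0, livestock_emissions = 0,
                      growth = list(managed = c(scale = 0, midpoint = 22, slope = 7),
                                    broadleaved = c(scale = 0, midpoint = 35, slope = 10)))
  hab <- rep(4L, 9)
  ls_a <- manual_landscape(3, 3, 1L)    # arable cells
  ls_p <- manual_landscape(3, 3, 2L)    # pasture cells
  cb_a <- carbon_benefit(ls_a, cp, hab)
  cb_p <- carbon_benefit(ls_p, cp, hab)
  expect_equal(cb_a[, "pasture"], -cb_p[, "arable"])
})

test_that("peat cells carry the state flux of the target category", {
  cp <- carbon_params()
  ls1 <- manual_landscape(3, 3, 2L, peat = TRUE,
                          subhabitat = rep(NA_integer_, 9))
  hab <- rep(match("fenbog", seminatural_subhabitats()), 9)
  cb <- carbon_benefit(ls1, cp, hab)
  # pasture -> pasture on peat: livestock term plus drained-pasture flux
  expect_equal(cb[, "pasture"],
               rep((-7.62 + cp$peat_flux[["pasture"]]) * 25, 9))
})

test_that("outlier smoothing replaces only flagged cells with neighbour means", {
  # constant surface: zero IQR flags nothing
  expect_identical(smooth_outliers(matrix(5, 3, 3)), matrix(5, 3, 3))
  # centre spike replaced by the mean of its eight 1-valued neighbours
  m <- matrix(1, 3, 3); m[2, 2] <- 1000
  expect_equal(smooth_outliers(m), matrix(1, 3, 3))
  # non-finite neighbours are excluded from the replacement mean
  m2 <- matrix(c(1, 2, 1, 2, 1000, NA, 1, 2, 1), 3, 3)
  sm <- smooth_outliers(m2)
  expect_equal(sm[2, 2], mean(c(1, 2, 1, 2, 1, 2, 1)))
  expect_true(is.na(sm[3, 2]))
  # surfaces smaller than 9 cells are rejected
  expect_error(smooth_outliers(matrix(1, 2, 2)), "smoothing error")
})

test_that("outlier smoothing is idempotent when no new outliers appear", {
  set.seed(42)
  m <- matrix(runif(100, 10, 20), 10, 10)
  m[c(5, 50, 95)] <- c(120, -80, 200)
  once <- smooth_outliers(m)
  # premise: the first pass created no new outliers
  expect_identical(smooth_outliers(once), once)
})

test_that("production benefits follow the suitability threshold and zero rules", {
  suit <- c(19, 20, 50, 0, 100, 19.99, 20.01, 35, 60)
  ls1 <- manual_landscape(3, 3, 2L, pasture_suitability = suit,
                          pasture_revenue = 300)
  pb <- production_benefit(ls1)
  expect_equal(pb[, "pasture"] > 0, suit >= 20)
  # semi-natural habitat never produces
  expect_equal(pb[, "seminatural"], rep(0, 9))
  # zero forest growth means zero timber revenue
  cp0 <- carbon_params(growth = list(managed = c(scale = 0, midpoint = 22, slope = 7),
                                     broadleaved = c(scale = 0, midpoint = 35, slope = 10)))
  pb0 <- production_benefit(ls1, cparams = cp0)
  expect_equal(pb0[, "plantation"], rep(0, 9))
  expect_true(all(pb >= 0))
})

test_that("raising one cell's arable revenue only raises that cell's arable benefit", {
  set.seed(17)
  y <- runif(9, 400, 600)   # spread keeps the raised value inside the IQR fence
  ls_lo <- manual_landscape(3, 3, 1L, arable_yield = y)
  y2 <- y; y2[5] <- y[5] + 50
  ls_hi <- manual_landscape(3, 3, 1L, arable_yield = y2)
  lo <- production_benefit(ls_lo); hi <- production_benefit(ls_hi)
  expect_gt(hi[5, "arable"], lo[5, "arable"])
  expect_equal(hi[-5, "arable"], lo[-5, "arable"])
})

test_that("biodiversity combines occurrence and condition by geometric mean", {
  n <- 9
  # occurrence sums: cell 1 carries the global max under seminatural,
  # cell 2 the global min everywhere
  occ <- array(0.5, dim = c(n, 1, 4), dimnames = list(NULL, NULL, lu_categories()))
  occ[2, 1, ] <- 0
  occ[1, 1, "seminatural"] <- 1
  ls1 <- manual_landscape(3, 3, 1L, occurrence = occ)
  bb <- biodiversity_benefit(ls1, habitat_assignment = rep(4L, n))
  # S_norm = 0 annihilates the geometric mean whatever the condition
  expect_equal(unname(bb[2, ]), rep(0, 4))
  # S_norm = 1 at the seminatural maximum of an arable cell: newly created
  # semi-natural condition 0.33 applies
  expect_equal(unname(bb[1, "seminatural"]), sqrt(1 * 0.33))
  expect_true(all(bb >= 0 & bb <= 1))
})

test_that("sqrt(condition) arithmetic and existing > new semi-natural ordering hold", {
  n <- 9
  occ <- array(1, dim = c(n, 1, 4), dimnames = list(NULL, NULL, lu_categories()))
  occ[1, 1, ] <- 0  # pins the global min so S_norm = 1 elsewhere
  # identical occurrence, one cell existing grassland vs one cell arable
  cur <- rep(1L, n); cur[5] <- 4L
  sub <- rep(NA_integer_, n); sub[5] <- match("heath", seminatural_subhabitats())
  ls1 <- manual_landscape(3, 3, cur, subhabitat = sub, occurrence = occ)
  bb <- biodiversity_benefit(ls1, habitat_assignment = rep(4L, n))
  expect_equal(unname(bb[2, "arable"]), sqrt(0.08))   # approx 0.2828
  # established heath (0.45) beats newly created semi-natural (0.33)
  expect_equal(unname(bb[5, "seminatural"]), sqrt(0.45))
  expect_gt(bb[5, "seminatural"], bb[2, "seminatural"])
  expect_equal(unname(bb[2, "seminatural"]), sqrt(0.33))
})

test_that("benefit maps assemble with shape checks and full coverage", {
  ls1 <- generate_landscape(synth_config(10, 10, seed = 4, n_species = 2))
  maps <- compute_benefit_maps(ls1)
  expect_equal(dim(maps$raw), c(100L, 4L, 3L))
  expect_true(all(is.finite(maps$raw[maps$convertible, , ])))
  expect_true(all(maps$raw[, , "biodiversity"] >= 0 &
                    maps$raw[, , "biodiversity"] <= 1))
  expect_true(all(maps$raw[, , "production"] >= 0))
  bad <- matrix(0, 99, 4)
  expect_error(assemble_benefit_maps(bad, maps$raw[, , 2], maps$raw[, , 3], ls1),
               "alignment error")
})
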