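test_that("judgment matrix validation catches malformed input", {
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  m <- diag(3); m[1, 2] <- 3; m[2, 1] <- 0.5
  expect_error(judgment_matrix(m), "positive|reciprocal")
  m2 <- matrix(c(1, 2, 3, 1), 2, 2)
  expect_error(judgment_matrix(m2), "reciprocal")
  m3 <- matrix(c(1, 1 / 12, 12, 1), 2, 2)
  expect_error(judgment_matrix(m3), "1/9")
})

test_that("AHP weights recover exact ratios on consistent matrices", {
  u <- judgment_matrix(matrix(1, 3, 3))
  expect_equal(unname(ahp_weights(u)), rep(1 / 3, 3))
  m <- judgment_matrix(matrix(c(1, 1 / 3, 3, 1), 2, 2))
  expect_equal(unname(ahp_weights(m)), c(0.75, 0.25))
  expect_equal(unname(ahp_weights(m, "eigenvector")), c(0.75, 0.25))
  # methods agree exactly on any consistent matrix w_i/w_j = a_ij
  w0 <- c(0.5, 0.3, 0.2)
  cm <- judgment_matrix(outer(w0, w0, "/"))
  expect_equal(unname(ahp_weights(cm)), w0, tolerance = 1e-12)
  expect_equal(unname(ahp_weights(cm, "eigenvector")), w0, tolerance = 1e-9)
})

test_that("the default six-factor matrix reproduces the published weights", {
  w <- ahp_weights(default_judgment_matrix())
  expect_equal(round(unname(w), 4),
               c(0.4289, 0.0437, 0.0604, 0.0604, 0.2033, 0.2033))
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("consistency ratio behaves on consistent, published and random matrices", {
  w0 <- c(0.4, 0.35, 0.15, 0.1)
  cm <- judgment_matrix(outer(w0, w0, "/"))
  cons <- consistency_ratio(cm)
  expect_equal(cons$lambda_max, 4, tolerance = 1e-10)
  expect_equal(cons$CR, 0, tolerance = 1e-10)
  cons6 <- consistency_ratio(default_judgment_matrix())
  expect_lt(cons6$CR, 0.1)
  expect_lt(abs(cons6$CR - 0.0816), 0.001)
  expect_error(consistency_ratio(judgment_matrix(matrix(1, 2, 2))), "n < 3")
  # lambda_max from the power method agrees with a dense eigensolver
  set.seed(91)
  for (rep in 1:5) {
    m <- diag(5)
    for (i in 1:4) for (j in (i + 1):5) {
      v <- sample(c(1 / (9:2), 1:9), 1)
      m[i, j] <- v; m[j, i] <- 1 / v
    }
    jm <- judgment_matrix(m)
    lam_eig <- max(Re(eigen(m)$values))
    expect_equal(consistency_ratio(jm, "eigenvector")$lambda_max, lam_eig,
                 tolerance = 1e-6)
  }
})

test_that("factor reclassification follows the published bands", {
  sch <- default_resistance_scheme()
  nd <- function(x) reclassify_factor(grid_raster(matrix(x, 1, 1)), sch$ndvi)$values[1, 1]
  expect_equal(nd(0.85), 1)
  expect_equal(nd(-0.2), 100)
  expect_equal(nd(1), 1)          # closed top band
  expect_equal(nd(0.2), 350)      # half-open: 0.2 belongs to [0.2, 0.4)
  sl <- function(x) reclassify_factor(grid_raster(matrix(x, 1, 1)), sch$slope)$values[1, 1]
  expect_equal(sl(0), 100)        # lower edge inclusive
  expect_equal(sl(4.999), 100)
  expect_equal(sl(5), 200)
  lu <- function(x) reclassify_factor(grid_raster(matrix(x, 1, 1)), sch$land_use)$values[1, 1]
  expect_equal(lu(landcover_codes()[["coal_mine"]]), 500)
  expect_equal(lu(landcover_codes()[["vegetation"]]), 1)
  expect_equal(lu(landcover_codes()[["water"]]), 50)
  expect_error(reclassify_factor(grid_raster(matrix(9, 2, 2)), sch$land_use),
               "cell \\(1, 1\\)")
  expect_error(reclassify_factor(grid_raster(matrix(1.5, 1, 1)), sch$ndvi),
               "outside all bands")
  r <- grid_raster(matrix(c(0.5, NA), 1, 2))
  expect_true(is.na(reclassify_factor(r, sch$ndvi)$values[1, 2]))
})

test_that("weighted overlay is the convex combination of factor surfaces", {
  sch <- default_resistance_scheme()
  w <- sch$weights
  one <- function(x) grid_raster(matrix(x, 1, 1))
  factors <- list(
    land_use = reclassify_factor(one(landcover_codes()[["vegetation"]]), sch$land_use),
    ndvi = reclassify_factor(one(0.9), sch$ndvi),
    slope = reclassify_factor(one(2), sch$slope),
    dem = reclassify_factor(one(250), sch$dem),
    dist_road = reclassify_factor(one(900), sch$dist_road),
    dist_mine = reclassify_factor(one(1200), sch$dist_mine))
  out <- weighted_overlay(factors, w)
  # hand arithmetic over the published rows: 1, 1, 100, 100, 100, 100
  expect_equal(out$values[1, 1],
               1 * w[["land_use"]] + 1 * w[["ndvi"]] + 100 * w[["slope"]] +
               100 * w[["dem"]] + 100 * w[["dist_road"]] + 100 * w[["dist_mine"]])
  # with the published 4-dp weights the same cell evaluates to 53.2126
  w4 <- round(w, 4)
  expect_equal(round(weighted_overlay(factors, w4)$values[1, 1], 4), 53.2126)
  # all factors at the ceiling collapse to the ceiling (weights sum to 1)
  top <- lapply(factors, function(f) grid_raster(matrix(500, 1, 1)))
  names(top) <- names(factors)
  expect_equal(weighted_overlay(top, w)$values[1, 1], 500)
  # permuting the factor list leaves the surface unchanged
  expect_equal(weighted_overlay(rev(factors), w)$values, out$values)
  expect_error(weighted_overlay(factors[1:5], w), "missing factor")
  expect_error(weighted_overlay(factors, w[1:3]), "missing weight")
})

test_that("the overlay surface stays within the per-factor resistance range", {
  set.seed(92)
  sch <- default_resistance_scheme()
  s <- generate_scene(scene_params(shape = c(40, 40), seed = 14))
  factors <- list(
    land_use = reclassify_factor(s$landcover, sch$land_use),
    ndvi = reclassify_factor(s$ndvi, sch$ndvi),
    slope = reclassify_factor(s$slope, sch$slope),
    dem = reclassify_factor(s$dem, sch$dem),
    dist_road = reclassify_factor(distance_to_features(s$roads), sch$dist_road),
    dist_mine = reclassify_factor(distance_to_features(s$mines), sch$dist_mine))
  out <- weighted_overlay(factors, sch$weights)
  lo <- do.call(pmin, lapply(factors, function(f) f$values))
  hi <- do.call(pmax, lapply(factors, function(f) f$values))
  expect_true(all(out$values >= lo - 1e-9 & out$values <= hi + 1e-9))
})
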