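test_that("uniform-grid cost distance matches the closed forms", {
  R <- mk_raster(matrix(2, 9, 9))
  cd <- cost_distance(R, cbind(5, 5))
  expect_equal(cd$accumulated$values[5, 5], 0)
  expect_equal(cd$accumulated$values[5, 8], 6)            # 3 orthogonal steps x 2
  expect_equal(cd$accumulated$values[6, 6], 2 * sqrt(2))  # one diagonal step
  expect_equal(cd$accumulated$values[1, 1], 8 * sqrt(2))  # pure diagonal run
  expect_error(cost_distance(R, integer(0)), "no source")
  Rna <- R; Rna$values[] <- NA
  expect_error(cost_distance(Rna, cbind(5, 5)), "impassable")
})

test_that("accumulated costs equal an independent Bellman-Ford oracle", {
  set.seed(101)
  for (rep in 1:15) {
    R <- matrix(runif(400, 0.5, 10), 20, 20)
    if (rep %% 3 == 0) R[sample(400, 30)] <- NA     # impassable pockets
    src <- sample(which(!is.na(R)), sample(1:3, 1))
    cd <- cost_distance(grid_raster(R, cell_size = 10), src)
    oracle <- oracle_cost_distance(R, src)
    got <- cd$accumulated$values
    got[is.na(got)] <- Inf
    oracle[is.na(R)] <- Inf
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("cost distance is symmetric and respects the triangle inequality", {
  set.seed(102)
  R <- grid_raster(matrix(runif(225, 1, 5), 15, 15), cell_size = 10)
  cells <- sample(225, 3)
  d <- vapply(cells, function(a) cost_distance(R, a)$accumulated$values[cells],
              numeric(3))
  expect_equal(d, t(d), tolerance = 1e-9)
  expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-9)
  expect_lte(d[2, 1], d[2, 3] + d[3, 1] + 1e-9)
  # raising resistance anywhere never lowers any accumulated cost
  R2 <- R
  R2$values[5:8, 5:8] <- R2$values[5:8, 5:8] * 4
  a1 <- cost_distance(R, cells[1])$accumulated$values
  a2 <- cost_distance(R2, cells[1])$accumulated$values
  expect_true(all(a2 >= a1 - 1e-9))
})

test_that("least-cost paths are traced correctly", {
  R <- mk_raster(matrix(1, 7, 11))
  cd <- cost_distance(R, cbind(4, 2))
  lcp <- least_cost_path(cd, cbind(4, 10))
  expect_true(all(lcp$cells[, 1] == 4))                  # straight row
  expect_equal(lcp$cost, 8)
  expect_equal(lcp$length_km, 8 * 10 / 1000)
  # destination inside the source set -> zero-length path
  lcp0 <- least_cost_path(cd, cbind(4, 2))
  expect_equal(nrow(lcp0$cells), 1)
  expect_equal(lcp0$cost, 0)
  # a wall with one gap forces the route through the gap
  W <- matrix(1, 9, 9); W[, 5] <- 1000; W[5, 5] <- 1
  cdw <- cost_distance(grid_raster(W, cell_size = 10), cbind(1, 1))
  lw <- least_cost_path(cdw, cbind(9, 9))
  crossing <- lw$cells[lw$cells[, 2] == 5, , drop = FALSE]
  expect_true(all(crossing[, 1] == 5))
  oracle <- oracle_cost_distance(W, lin_src <- (1 - 1) * 9 + 1)
  expect_equal(lw$cost, oracle[9, 9], tolerance = 1e-9)
  # unreachable destination is a clear error
  Rw <- matrix(1, 5, 5); Rw[, 3] <- NA
  cdu <- cost_distance(grid_raster(Rw), cbind(3, 1))
  expect_error(least_cost_path(cdu, cbind(3, 5)), "unreachable")
  # path cost always equals the sum of its move costs
  set.seed(103)
  Rr <- matrix(runif(144, 1, 8), 12, 12)
  cdr <- cost_distance(grid_raster(Rr), cbind(1, 1))
  lr <- least_cost_path(cdr, cbind(12, 12))
  steps <- diff(lr$cells)
  move_costs <- vapply(seq_len(nrow(steps)), function(i) {
    a <- lr$cells[i, ]; b <- lr$cells[i + 1, ]
    L <- if (all(abs(steps[i, ]) == 1)) sqrt(2) else 1
    (Rr[a[1], a[2]] + Rr[b[1], b[2]]) / 2 * L
  }, numeric(1))
  expect_equal(lr$cost, sum(move_costs), tolerance = 1e-6)
})

three_sources <- function() {
  # three 2x2 patches on one row of a uniform landscape
  lapply(list(c(3, 2), c(3, 12), c(3, 22)), function(p) {
    cells <- as.matrix(expand.grid(row = p[1] + 0:1, col = p[2] + 0:1))
    list(id = p[2], cells = cells, area_ha = 0.04)
  })
}

test_that("corridor building connects pairs and prunes redundant paths", {
  R <- mk_raster(matrix(1, 7, 25))
  src <- three_sources()
  cs <- build_corridors(src, R, prune_overlap = 0.8)
  expect_equal(nrow(cs$corridors), 3)        # all unordered pairs attempted
  expect_equal(cs$n_corridors, 2)            # the long A-C path is redundant
  long <- cs$corridors[cs$corridors$from == 2 & cs$corridors$to == 22, ]
  expect_false(long$retained)
  # pruning disabled keeps every pair
  expect_equal(build_corridors(src, R, prune_overlap = 1.01)$n_corridors, 3)
  # two sources always give exactly one corridor
  expect_equal(build_corridors(src[c(1, 3)], R)$n_corridors, 1)
  expect_error(build_corridors(src[1], R), "at least two")
})

test_that("disconnected source pairs are skipped with a warning", {
  R <- matrix(1, 7, 25); R[, 17] <- NA
  src <- three_sources()
  w <- capture_warnings(cs <- build_corridors(src, grid_raster(R),
                                              prune_overlap = 0.8))
  expect_length(w, 2)                        # A-C and B-C cross the barrier
  expect_true(all(grepl("disconnected", w)))
  expect_equal(nrow(cs$corridors), 1)        # only the pair west of the barrier
})

test_that("D8 ridgelines match the definition on canonical terrain", {
  # plane descending eastward: only the west (highest) column receives no flow
  dem <- mk_raster(matrix(rep(50 - (1:10) * 2, each = 10), 10, 10))
  rg <- extract_ridgelines(dem)
  expect_true(all(rg$values[, 1] == 1))
  expect_equal(sum(rg$values), 10)
  # tent with a north-south crest: the crest column is ridge
  prof <- c(1:5, 4:1)
  tent <- mk_raster(matrix(rep(prof, each = 9), 9, 9))
  rt <- extract_ridgelines(tent)
  expect_true(all(rt$values[, 5] == 1))
  # bowl: the rim is ridge, the centre is not
  xy <- expand.grid(r = 1:9, cl = 1:9)
  bowl <- matrix((xy$r - 5)^2 + (xy$cl - 5)^2, 9, 9)
  rb <- extract_ridgelines(mk_raster(bowl))
  expect_equal(rb$values[5, 5], 0)
  expect_true(all(rb$values[1, ] == 1) && all(rb$values[9, ] == 1))
  expect_warning(extract_ridgelines(mk_raster(matrix(3, 5, 5))), "flat")
})

test_that("D8 receivers and accumulation equal a cell-by-cell oracle", {
  set.seed(104)
  for (rep in 1:5) {
    z <- matrix(stats::rnorm(15 * 15), 15, 15)
    z <- as.matrix(EBImage::gblur(z, sigma = 2)) * 40 + 100
    rg <- extract_ridgelines(mk_raster(z))
    oracle <- oracle_d8(z)
    expect_equal(attr(rg, "accumulation"), oracle$accumulation)
    expect_identical(unname(which(rg$values == 1)),
                     which(oracle$accumulation == 0))
  }
})

test_that("ecological nodes appear where corridors meet ridgelines", {
  R <- mk_raster(matrix(1, 7, 25))
  src <- three_sources()
  cs <- build_corridors(src, R, prune_overlap = 0.8)
  # synthetic ridge: one vertical column the corridors must cross
  ridge_m <- matrix(0, 7, 25); ridge_m[, 7] <- 1
  nodes <- identify_nodes(cs, mk_raster(ridge_m), merge_radius = 3)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$col, 7)
  # empty ridge raster -> no nodes
  n0 <- identify_nodes(cs, mk_raster(matrix(0, 7, 25)), 3)
  expect_equal(nrow(n0), 0)
  # a run of consecutive ridge cells along the corridor merges to its centre
  ridge_run <- matrix(0, 7, 25); ridge_run[3, 9:13] <- 1; ridge_run[4, 9:13] <- 1
  nr <- identify_nodes(cs, mk_raster(ridge_run), merge_radius = 3)
  expect_equal(nrow(nr), 1)
  expect_equal(nr$col, 11)
})
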