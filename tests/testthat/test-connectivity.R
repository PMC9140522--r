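two_patch_graph <- function(d, a = 10, AL = 100) {
  p <- lapply(1:2, function(i) list(id = i, cells = cbind(row = i, col = 1),
                                    area_ha = a))
  patch_graph(p, AL = AL, dist = matrix(c(0, d, d, 0), 2, 2))
}

test_that("patch extraction labels 8-connected core components", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 1; m[7:9, 7:9] <- 1
  seg <- mspa_segment(mk_raster(m), 1)
  # force patches straight from a class raster with two 3x3 cores
  cls <- matrix(0, 10, 10); cls[2:4, 2:4] <- 1; cls[7:9, 7:9] <- 1
  patches <- extract_patches(grid_raster(cls, cell_size = 10))
  expect_length(patches, 2)
  expect_equal(patches[[1]]$area_ha, 0.09)
  # diagonal touch merges into one patch
  cls2 <- matrix(0, 5, 5); cls2[2, 2] <- 1; cls2[3, 3] <- 1
  expect_length(extract_patches(grid_raster(cls2, cell_size = 10)), 1)
  # component count equals a flood-fill oracle on random rasters
  set.seed(81)
  for (rep in 1:20) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    cls <- matrix(0, 20, 20); cls[m] <- 1
    expect_length(extract_patches(grid_raster(cls, cell_size = 10)),
                  oracle_component_count(m))
  }
})

test_that("patch distances equal the exhaustive pairwise scan", {
  cls <- matrix(0, 8, 8); cls[2, 2] <- 1; cls[2, 4] <- 1
  p <- extract_patches(grid_raster(cls, cell_size = 10))
  d <- patch_distances(p)
  expect_equal(d[1, 2], 20)
  expect_equal(diag(d), c(0, 0))
  set.seed(82)
  for (rep in 1:10) {
    m <- matrix(runif(225) < 0.15, 15, 15)
    cls <- matrix(0, 15, 15); cls[m] <- 1
    p <- extract_patches(grid_raster(cls, cell_size = 10))
    if (length(p) < 2) next
    d <- patch_distances(p)
    for (i in seq_along(p)) for (j in seq_along(p)) {
      if (i < j) {
        expect_equal(d[i, j],
                     oracle_patch_dist(p[[i]]$cells, p[[j]]$cells, 10),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("IIC and PC closed forms hold exactly", {
  p1 <- list(list(id = 1, cells = cbind(row = 1, col = 1), area_ha = 10))
  g1 <- patch_graph(p1, AL = 100, dist = matrix(0, 1, 1))
  expect_equal(iic(g1), 0.01)                  # a^2 / AL^2
  expect_equal(pc(g1), 0.01)
  expect_equal(iic(two_patch_graph(400)), 0.03)   # linked: nl = 1
  expect_equal(iic(two_patch_graph(900)), 0.02)   # unlinked
  expect_equal(pc(two_patch_graph(500)), 0.03)    # kernel anchor p = 0.5
  expect_equal(delta_importance(two_patch_graph(500), "PC"),
               c(100 * (0.03 - 0.01) / 0.03, 100 * (0.03 - 0.01) / 0.03))
  expect_equal(delta_importance(two_patch_graph(400), "IIC"),
               rep(100 * (0.03 - 0.01) / 0.03, 2))
  expect_equal(delta_importance(g1, "PC"), 100)   # removal zeroes PC
  expect_equal(iic(patch_graph(list(), AL = 100)), 0)
})

test_that("indices match exhaustive oracles on random graphs", {
  set.seed(83)
  AL <- 1000
  for (rep in 1:30) {
    n <- sample(2:7, 1)
    gi <- random_patch_graph_inputs(n)
    g <- patch_graph(gi$patches, AL = AL, dist = gi$dist)
    links <- gi$dist <= 500; diag(links) <- FALSE
    nl <- oracle_hops(links)
    expect_equal(iic(g), oracle_iic(gi$areas, nl, AL), tolerance = 1e-9)
    p_star <- oracle_pstar(0.5^(gi$dist / 500))
    expect_equal(pc(g), oracle_pc(gi$areas, p_star, AL), tolerance = 1e-9)
    # leave-one-out importance against recompute-from-scratch
    d_pc <- delta_importance(g, "PC")
    for (k in seq_len(n)) {
      keep <- setdiff(seq_len(n), k)
      pk <- oracle_pc(gi$areas[keep],
                      oracle_pstar(0.5^(gi$dist[keep, keep, drop = FALSE] / 500)),
                      AL)
      expect_equal(d_pc[k], 100 * (pc(g) - pk) / pc(g), tolerance = 1e-9)
    }
  }
})

test_that("indices are invariant to patch relabelling and bounded", {
  set.seed(84)
  gi <- random_patch_graph_inputs(6)
  g <- patch_graph(gi$patches, AL = 1000, dist = gi$dist)
  perm <- sample(6)
  g2 <- patch_graph(gi$patches[perm], AL = 1000,
                    dist = gi$dist[perm, perm])
  expect_equal(iic(g), iic(g2), tolerance = 1e-12)
  expect_equal(pc(g), pc(g2), tolerance = 1e-12)
  expect_true(iic(g) > 0 && iic(g) <= 1)
  expect_true(pc(g) > 0 && pc(g) <= 1)
  # stretching one pairwise distance can never raise PC
  d3 <- gi$dist; d3[1, 2] <- d3[2, 1] <- d3[1, 2] * 10
  g3 <- patch_graph(gi$patches, AL = 1000, dist = d3)
  expect_lte(pc(g3), pc(g) + 1e-12)
})

test_that("source selection keeps the top-k by dPC with stated tie-breaks", {
  mkp <- function(id, a) list(id = id, cells = cbind(row = id, col = 1),
                              area_ha = a)
  patches <- list(mkp(1, 5), mkp(2, 9), mkp(3, 9), mkp(4, 2))
  sel <- select_sources(patches, dpc = c(10, 50, 50, 1), k = 2)
  expect_equal(vapply(sel, `[[`, numeric(1), "id"), c(2, 3)) # tied dPC -> id order
  sel2 <- select_sources(patches, dpc = c(10, 50, 50, 1), k = 3)
  expect_equal(vapply(sel2, `[[`, numeric(1), "id"), c(2, 3, 1))
  sel3 <- select_sources(list(mkp(1, 5), mkp(2, 1), mkp(3, 7)),
                         dpc = c(4, 4, 4), k = 2)
  expect_equal(vapply(sel3, `[[`, numeric(1), "id"), c(3, 1)) # larger area first
  expect_warning(select_sources(patches, c(1, 2, 3, 4), k = 10), "only 4")
  expect_error(select_sources(list(), numeric(0)), "no ecological sources")
})
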