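#' Land-cover class codes
#'
#' The six land-use classes used throughout the pipeline: 1 water bodies,
#' 2 vegetation, 3 construction land, 4 coal-mine land, 5 unused land,
#' 6 other.
#'
#' @return named integer vector of codes.
#' @export
landcover_codes <- function() {
  c(water = 1L, vegetation = 2L, construction = 3L, coal_mine = 4L,
    unused = 5L, other = 6L)
}

#' Parameters for a synthetic landscape scene
#'
#' Describes an arid-region scene in which bare/unused land dominates
#' (the default cover fractions put >95% of the area in unused + other,
#' matching the kind of desert-steppe mosaic the pipeline targets), with
#' vegetation and water forming spatially contiguous patches, smooth terrain,
#' a few crossing roads and scattered mine sites. The seed fully determines
#' every generated layer.
#'
#' @param shape integer (rows, cols).
#' @param cell_size metres per cell.
#' @param seed master integer seed.
#' @param cover_fractions named fractions over the six classes, summing to 1.
#' @param patchiness correlation length of the cover random field, in cells.
#' @param n_roads,n_mines counts of road polylines and mine sites.
#' @param relief_amplitude total relief (max - min elevation target), metres.
#' @param base_elevation elevation floor, metres.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(shape = c(300, 300), cell_size = 10, seed = 1,
                         cover_fractions = c(water = 0.005, vegetation = 0.03,
                                             construction = 0.01, coal_mine = 0.005,
                                             unused = 0.90, other = 0.05),
                         patchiness = 8, n_roads = 3, n_mines = 4,
                         relief_amplitude = 150, base_elevation = 200) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) stop("`shape` must be (rows, cols) >= 1")
  codes <- names(landcover_codes())
  if (!setequal(names(cover_fractions), codes)) {
    stop("`cover_fractions` must be named over: ", paste(codes, collapse = ", "))
  }
  cover_fractions <- cover_fractions[codes]
  if (abs(sum(cover_fractions) - 1) > 1e-9) stop("cover fractions must sum to 1")
  if (any(cover_fractions < 0)) stop("cover fractions must be non-negative")
  if (patchiness < 1) stop("`patchiness` (correlation length) must be >= 1 cell")
  if (n_roads < 0 || n_mines < 0) stop("`n_roads` and `n_mines` must be >= 0")
  if (relief_amplitude < 0) stop("`relief_amplitude` must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")
  structure(list(shape = shape, cell_size = cell_size, seed = seed,
                 cover_fractions = cover_fractions, patchiness = patchiness,
                 n_roads = n_roads, n_mines = n_mines,
                 relief_amplitude = relief_amplitude,
                 base_elevation = base_elevation),
            class = "scene_params")
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

# separable Gaussian convolution with edge replication; unlike kernel-based
# image filters this accepts any sigma relative to the grid size
gaussian_smooth <- function(z, sigma) {
  rad <- ceiling(3 * sigma)
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(m) {  # along rows (i.e. down each column)
    nr <- nrow(m)
    pad <- m[c(rep(1, rad), 1:nr, rep(nr, rad)), , drop = FALSE]
    out <- matrix(0, nr, ncol(m))
    for (t in seq_along(k)) {
      out <- out + k[t] * pad[(t - 1) + 1:nr, , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(z))))
}

# smoothed Gaussian random field (white noise smoothed at sigma = corlen)
gaussian_field <- function(rows, cols, corlen) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (corlen > 0) z <- gaussian_smooth(z, corlen)
  z
}

#' Generate a categorical land-cover raster
#'
#' Thresholds a smoothed Gaussian random field at the rank quantiles implied
#' by the target cover fractions, so that water and vegetation form
#' contiguous patches (water occupies the lowest field values, vegetation the
#' next band, mirroring moisture-driven zonation). Deterministic given the
#' seed; realized class counts match the targets to within one cell.
#'
#' @param params a [scene_params] object.
#' @return categorical [grid_raster] of land-cover codes.
#' @export
generate_landcover <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$shape[1]; nc <- params$shape[2]
  fld <- with_seed(params$seed + 101L,
                   gaussian_field(nr, nc, params$patchiness))
  # assign classes along the field's rank order: low = wet, high = dry
  ord <- order(as.vector(fld), seq_along(fld))
  class_order <- c("water", "vegetation", "unused", "other", "construction",
                   "coal_mine")
  fr <- params$cover_fractions[class_order]
  n <- nr * nc
  bounds <- round(cumsum(fr) * n)
  counts <- diff(c(0, bounds))
  codes_by_rank <- rep(landcover_codes()[class_order], counts)
  length(codes_by_rank) <- n                     # guard against rounding
  codes_by_rank[is.na(codes_by_rank)] <- landcover_codes()["unused"]
  v <- integer(n)
  v[ord] <- codes_by_rank
  grid_raster(matrix(as.numeric(v), nr, nc), params$cell_size,
              c(0, nr * params$cell_size), "synthetic")
}

#' Generate terrain (DEM and slope)
#'
#' DEM = base elevation + relief_amplitude x (0.7 smoothed field + 0.3
#' west-east regional gradient), so relief scales linearly with the amplitude
#' and a zero amplitude gives a perfectly flat scene. Slope is derived with
#' [slope_from_dem].
#'
#' @param params a [scene_params] object.
#' @return list with `dem` and `slope` rasters.
#' @export
generate_terrain <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$shape[1]; nc <- params$shape[2]
  fld <- with_seed(params$seed + 202L,
                   gaussian_field(nr, nc, max(params$patchiness * 2, 4)))
  rng <- diff(range(fld))
  fn <- if (rng > 0) (fld - min(fld)) / rng else fld * 0
  grad <- matrix(rep((seq_len(nc) - 1) / max(nc - 1, 1), each = nr), nr, nc)
  dem_v <- params$base_elevation + params$relief_amplitude * (0.7 * fn + 0.3 * grad)
  dem <- grid_raster(dem_v, params$cell_size, c(0, nr * params$cell_size),
                     "synthetic")
  list(dem = dem, slope = if (nr >= 3 && nc >= 3) slope_from_dem(dem) else
    grid_raster(dem_v * 0, params$cell_size, dem$origin, dem$crs_tag))
}

#' Generate an NDVI raster consistent with land cover
#'
#' Per-class Gaussian draws: vegetation mean 0.5, water mean -0.3, all other
#' classes mean 0.05, each with standard deviation 0.05, clipped to [-1, 1].
#'
#' @param landcover categorical land-cover raster.
#' @param seed integer seed.
#' @return NDVI [grid_raster].
#' @export
generate_ndvi <- function(landcover, seed = 1) {
  stopifnot(is_grid_raster(landcover))
  v <- landcover$values
  known <- landcover_codes()
  if (!all(v[!is.na(v)] %in% known)) {
    bad <- setdiff(unique(v[!is.na(v)]), known)
    stop("unknown land-cover code(s): ", paste(bad, collapse = ", "))
  }
  means <- c(`1` = -0.3, `2` = 0.5, `3` = 0.05, `4` = 0.05, `5` = 0.05,
             `6` = 0.05)
  mu <- matrix(means[as.character(v)], nrow(v), ncol(v))
  ndvi <- with_seed(as.integer(seed) + 404L,
                    mu + matrix(stats::rnorm(length(v), sd = 0.05),
                                nrow(v), ncol(v)))
  ndvi <- pmin(pmax(ndvi, -1), 1)
  ndvi[is.na(v)] <- NA
  grid_raster(ndvi, landcover$cell_size, landcover$origin, landcover$crs_tag,
              landcover$nodata)
}

# 8-connected Bresenham rasterization of a segment between two cells
bresenham_cells <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; cl <- c0
  out <- matrix(0L, dr + dc + 1L, 2L)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(r, cl)
    if (r == r1 && cl == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; cl <- cl + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Generate infrastructure (roads and mine sites)
#'
#' Roads are random two-segment polylines crossing the scene, rasterized
#' 8-connectedly; mines are random point cells drawn away from water. Both
#' are burned into the land-cover raster (roads as construction land, mines
#' as coal-mine land) so downstream reclassification sees consistent inputs.
#'
#' @param params a [scene_params] object.
#' @param landcover land-cover raster to burn infrastructure into.
#' @return list with `roads` (0/1 raster), `road_lines` (list of world-coord
#'   vertex matrices), `mines` (0/1 raster), `mine_points` (world-coord
#'   matrix), and the updated `landcover`.
#' @export
generate_infrastructure <- function(params, landcover) {
  stopifnot(inherits(params, "scene_params"), is_grid_raster(landcover))
  nr <- params$shape[1]; nc <- params$shape[2]
  lc <- landcover$values
  roads <- matrix(FALSE, nr, nc)
  road_lines <- list()
  mines <- matrix(FALSE, nr, nc)
  with_seed(params$seed + 303L, {
    if (params$n_roads > 0) {
      for (k in seq_len(params$n_roads)) {
        if (k %% 2 == 1) { # west-east crossing
          a <- c(sample.int(nr, 1), 1L); b <- c(sample.int(nr, 1), nc)
        } else {           # north-south crossing
          a <- c(1L, sample.int(nc, 1)); b <- c(nr, sample.int(nc, 1))
        }
        mid <- c(sample.int(nr, 1), sample.int(nc, 1))
        cells <- rbind(bresenham_cells(a[1], a[2], mid[1], mid[2]),
                       bresenham_cells(mid[1], mid[2], b[1], b[2]))
        roads[cbind(cells[, 1], cells[, 2])] <- TRUE
        verts <- rbind(a, mid, b)
        road_lines[[k]] <- cell_center_xy(landcover, verts[, 1], verts[, 2])
      }
    }
    if (params$n_mines > 0) {
      candidates <- which(lc != landcover_codes()["water"])
      if (length(candidates) < params$n_mines) candidates <- seq_along(lc)
      sel <- sample(candidates, params$n_mines)
      mines[sel] <- TRUE
    }
  })
  lc[roads] <- landcover_codes()["construction"]
  lc[mines] <- landcover_codes()["coal_mine"]
  mk <- function(m) grid_raster(m, landcover$cell_size, landcover$origin,
                                landcover$crs_tag, landcover$nodata)
  mi <- which(mines, arr.ind = TRUE)
  list(roads = mk(roads), road_lines = road_lines, mines = mk(mines),
       mine_points = if (nrow(mi)) cell_center_xy(landcover, mi[, 1], mi[, 2])
                     else matrix(numeric(0), 0, 2),
       landcover = mk(lc))
}

#' Generate a complete synthetic scene
#'
#' Runs land cover, infrastructure burning, NDVI and terrain generation from
#' one master seed (stage seeds are fixed offsets of it), returning a bundle
#' of mutually aligned layers.
#'
#' @param params a [scene_params] object.
#' @return list with `params`, `landcover`, `ndvi`, `dem`, `slope`, `roads`,
#'   `road_lines`, `mines`, `mine_points`.
#' @export
generate_scene <- function(params = scene_params()) {
  lc <- generate_landcover(params)
  infra <- generate_infrastructure(params, lc)
  ndvi <- generate_ndvi(infra$landcover, params$seed)
  terr <- generate_terrain(params)
  list(params = params, landcover = infra$landcover, ndvi = ndvi,
       dem = terr$dem, slope = terr$slope, roads = infra$roads,
       road_lines = infra$road_lines, mines = infra$mines,
       mine_points = infra$mine_points)
}
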