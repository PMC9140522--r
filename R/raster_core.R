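#' Single-band grid raster
#'
#' The universal carrier for every layer in the pipeline: a numeric matrix
#' with square cells, a top-left world origin, and a nodata sentinel used on
#' disk (nodata cells are held as `NA` in memory). Rows increase southward,
#' columns eastward.
#'
#' @param values numeric (or logical) matrix; logical input is coerced to 0/1.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, world coordinate (x, y) of the outer
#'   corner of cell (row 1, col 1), i.e. the top-left corner of the grid.
#' @param crs_tag opaque coordinate-reference identifier string.
#' @param nodata sentinel value used when the raster is written to disk.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size = 10, origin = c(0, 0),
                        crs_tag = "local", nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.logical(values)) {
    v <- values
    values <- matrix(0, nrow(v), ncol(v))
    values[v] <- 1
    values[is.na(v)] <- NA
  }
  if (!is.numeric(values)) stop("`values` must be numeric or logical")
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number")
  }
  if (length(origin) != 2 || any(!is.finite(origin))) {
    stop("`origin` must be two finite coordinates (x, y)")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_tag = as.character(crs_tag)[1],
         nodata = as.numeric(nodata)),
    class = "grid_raster"
  )
}

#' @rdname grid_raster
#' @param x object to test.
#' @export
is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d x %d cells, %.6g m cells, origin (%.6g, %.6g), crs '%s'\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2], x$crs_tag))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.6g, %.6g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' @export
plot.grid_raster <- function(x, main = "", ...) {
  v <- x$values
  # image() draws column-major bottom-up; transpose and flip rows so north is up
  graphics::image(t(v[nrow(v):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = main, axes = FALSE, ...)
  invisible(x)
}

# world coordinates of cell centres
cell_center_xy <- function(raster, row, col) {
  cbind(x = raster$origin[1] + (col - 0.5) * raster$cell_size,
        y = raster$origin[2] - (row - 0.5) * raster$cell_size)
}

#' Check that a set of rasters share one grid
#'
#' All layers entering a pipeline must agree in shape, cell size, origin and
#' CRS tag; any mismatch is an error (an "alignment error").
#'
#' @param ... `grid_raster` objects, or a single list of them.
#' @return invisibly `TRUE` on success.
#' @export
check_alignment <- function(...) {
  rs <- list(...)
  if (length(rs) == 1 && !is_grid_raster(rs[[1]])) rs <- rs[[1]]
  if (!length(rs)) return(invisible(TRUE))
  if (!all(vapply(rs, is_grid_raster, logical(1)))) {
    stop("alignment error: all layers must be grid_raster objects")
  }
  ref <- rs[[1]]
  for (i in seq_along(rs)[-1]) {
    r <- rs[[i]]
    bad <- character(0)
    if (!identical(dim(r$values), dim(ref$values))) bad <- c(bad, "shape")
    if (r$cell_size != ref$cell_size) bad <- c(bad, "cell_size")
    if (!isTRUE(all(abs(r$origin - ref$origin) < 1e-9))) bad <- c(bad, "origin")
    if (r$crs_tag != ref$crs_tag) bad <- c(bad, "crs_tag")
    if (length(bad)) {
      stop(sprintf("alignment error: layer %d differs in %s", i,
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Normalized difference vegetation index
#'
#' NDVI = (rho_NIR - rho_Red) / (rho_NIR + rho_Red), computed cellwise on two
#' aligned reflectance rasters. Cells where the denominator is zero, or where
#' either input is nodata, propagate as nodata; the result is bounded in
#' [-1, 1] for non-negative reflectances.
#'
#' @param nir,red near-infrared and red reflectance rasters (values >= 0).
#' @return NDVI `grid_raster`.
#' @export
compute_ndvi <- function(nir, red) {
  if (!is_grid_raster(nir) || !is_grid_raster(red)) {
    stop("inputs must be grid_raster objects")
  }
  check_alignment(nir, red)
  a <- nir$values
  b <- red$values
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("reflectances must be non-negative")
  }
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA
  grid_raster(out, nir$cell_size, nir$origin, nir$crs_tag, nir$nodata)
}

#' Euclidean distance to the nearest feature cell
#'
#' Cell-centre to cell-centre Euclidean distance (in metres) from every cell
#' to the nearest `TRUE`/non-zero cell of the feature raster; feature cells
#' get 0. Used for the distance-to-road and distance-to-mine resistance
#' factors.
#'
#' @param features boolean `grid_raster` (non-zero = feature; `NA` treated as
#'   non-feature). Must contain at least one feature cell.
#' @return distance `grid_raster` in metres.
#' @export
distance_to_features <- function(features) {
  if (!is_grid_raster(features)) stop("`features` must be a grid_raster")
  f <- !is.na(features$values) & features$values != 0
  if (!any(f)) stop("no feature cells: distance undefined")
  m <- matrix(1, nrow(f), ncol(f))
  m[f] <- 0                      # distmap: distance of non-zero cells to nearest zero
  d <- as.matrix(EBImage::distmap(m, metric = "euclidean")) * features$cell_size
  grid_raster(d, features$cell_size, features$origin, features$crs_tag,
              features$nodata)
}

#' Slope from a DEM (Horn stencil)
#'
#' Slope in degrees from a 3x3 finite-difference (Horn) stencil; border cells
#' use edge replication. Requires at least a 3x3 DEM.
#'
#' @param dem elevation `grid_raster` in metres.
#' @return slope `grid_raster` in degrees, values in [0, 90).
#' @export
slope_from_dem <- function(dem) {
  if (!is_grid_raster(dem)) stop("`dem` must be a grid_raster")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3x3 cells")
  cs <- dem$cell_size
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]     # edge replication
  a <- zp[1:nr,       1:nc      ]; b <- zp[1:nr,       2:(nc + 1)]; cc <- zp[1:nr,       3:(nc + 2)]
  d <- zp[2:(nr + 1), 1:nc      ];                                   f <- zp[2:(nr + 1), 3:(nc + 2)]
  g <- zp[3:(nr + 2), 1:nc      ]; h <- zp[3:(nr + 2), 2:(nc + 1)]; i <- zp[3:(nr + 2), 3:(nc + 2)]
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  gy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  grid_raster(slope, cs, dem$origin, dem$crs_tag, dem$nodata)
}

# linear index helpers (column-major, as R stores matrices)
lin_index <- function(row, col, nr) (col - 1L) * nr + row

# 8-neighbour offsets in the fixed clockwise scan order starting east
neighbor_offsets <- function() {
  list(E  = c(0L,  1L), SE = c(1L,  1L), S  = c(1L,  0L), SW = c(1L, -1L),
       W  = c(0L, -1L), NW = c(-1L, -1L), N = c(-1L, 0L), NE = c(-1L, 1L))
}

# shift a matrix by (dr, dc), filling exposed cells with `fill`
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
  sc <- max(1, 1 - dc):min(nc, nc - dc)
  out[sr, sc] <- m[sr + dr, sc + dc, drop = FALSE]
  out
}

# label connected components of a logical matrix (4- or 8-connectivity);
# labels are 1..k in row-major order of first occurrence, 0 elsewhere
label_components <- function(mask, conn = 8) {
  stopifnot(conn %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  n <- nr * nc
  mask[is.na(mask)] <- FALSE
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (conn == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  idx <- matrix(seq_len(n), nr, nc)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    if (nr - dr < 1 || nc - abs(dc) < 1) next
    rs <- if (dr > 0) 1:(nr - dr) else 1:nr
    cs <- if (dc > 0) 1:(nc - dc) else if (dc < 0) (1 - dc):nc else 1:nc
    a <- idx[rs, cs, drop = FALSE]
    b <- idx[rs + dr, cs + dc, drop = FALSE]
    keep <- mask[a] & mask[b]
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, nr, nc)
  if (any(mask)) {
    # renumber components 1..k in row-major order of first appearance
    rm_order <- as.vector(t(matrix(seq_len(n), nr, nc)))  # row-major scan
    cells_rm <- rm_order[mask[rm_order]]
    first <- unique(memb[cells_rm])
    lab[mask] <- match(memb[mask], first)
  }
  lab
}
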