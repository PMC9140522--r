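#' AHP pairwise judgment matrix
#'
#' Validates and tags an n x n positive reciprocal matrix on Saaty's 1-9
#' importance scale: unit diagonal, a_ji = 1/a_ij (tolerance 1e-9), entries
#' in [1/9, 9].
#'
#' @param x square numeric matrix.
#' @param labels optional factor labels for rows/columns.
#' @return the matrix with class `judgment_matrix`.
#' @export
judgment_matrix <- function(x, labels = NULL) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("judgment matrix must be square")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("judgment matrix entries must be positive")
  }
  if (any(abs(diag(x) - 1) > 1e-9)) stop("judgment matrix diagonal must be 1")
  if (max(abs(x * t(x) - 1)) > 1e-9) {
    stop("judgment matrix must be reciprocal (a_ji = 1/a_ij)")
  }
  if (any(x < 1 / 9 - 1e-9) || any(x > 9 + 1e-9)) {
    stop("judgment matrix entries must lie in [1/9, 9]")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("`labels` length must match the matrix")
    dimnames(x) <- list(labels, labels)
  }
  structure(x, class = c("judgment_matrix", "matrix"))
}

#' The default six-factor judgment matrix
#'
#' Pairwise comparisons of the six resistance factors (land use, NDVI,
#' slope, DEM, distance to road, distance to coal mine) expressing that land
#' use dominates, the two distance factors come next, and slope/DEM/NDVI
#' matter least.
#'
#' @return a [judgment_matrix].
#' @export
default_judgment_matrix <- function() {
  m <- rbind(
    c(1,     5, 7,     7,     3,     3),
    c(1 / 5, 1, 1 / 3, 1 / 3, 1 / 3, 1 / 3),
    c(1 / 7, 3, 1,     1,     1 / 5, 1 / 5),
    c(1 / 7, 3, 1,     1,     1 / 5, 1 / 5),
    c(1 / 3, 3, 5,     5,     1,     1),
    c(1 / 3, 3, 5,     5,     1,     1))
  judgment_matrix(m, labels = c("land_use", "ndvi", "slope", "dem",
                                "dist_road", "dist_mine"))
}

#' AHP factor weights
#'
#' Row geometric means normalized to sum 1 (the default), or the normalized
#' principal eigenvector. For a perfectly consistent matrix both methods
#' agree exactly.
#'
#' @param matrix a [judgment_matrix] (validated if a plain matrix is given).
#' @param method `"geometric_mean"` or `"eigenvector"`.
#' @return named weight vector summing to 1.
#' @export
ahp_weights <- function(matrix, method = c("geometric_mean", "eigenvector")) {
  if (!inherits(matrix, "judgment_matrix")) matrix <- judgment_matrix(matrix)
  method <- match.arg(method)
  m <- unclass(matrix)
  w <- if (method == "geometric_mean") {
    exp(rowMeans(log(m)))
  } else {
    e <- eigen(m)
    v <- Re(e$vectors[, which.max(Re(e$values))])
    if (sum(v) < 0) v <- -v
    v
  }
  w <- w / sum(w)
  names(w) <- rownames(m)
  w
}

# Saaty's classical random consistency indices, n = 1..15
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59)

#' AHP consistency ratio
#'
#' lambda_max is the mean of (A w)_i / w_i with w from [ahp_weights];
#' CI = (lambda_max - n)/(n - 1); CR = CI / RI(n) with Saaty's random index
#' table (RI(6) = 1.24). A matrix passes the coherence check when CR < 0.1.
#'
#' @param matrix a [judgment_matrix]; must be at least 3 x 3.
#' @param method weight derivation method passed to [ahp_weights].
#' @return list with `lambda_max`, `CI`, `CR`.
#' @export
consistency_ratio <- function(matrix, method = c("geometric_mean", "eigenvector")) {
  if (!inherits(matrix, "judgment_matrix")) matrix <- judgment_matrix(matrix)
  n <- nrow(matrix)
  if (n < 3) stop("consistency ratio undefined for n < 3")
  if (n > length(SAATY_RI)) stop("no random index tabulated for n = ", n)
  w <- ahp_weights(matrix, method)
  lambda_max <- mean((unclass(matrix) %*% w) / w)
  CI <- (lambda_max - n) / (n - 1)
  CR <- CI / SAATY_RI[n]
  list(lambda_max = lambda_max, CI = CI, CR = CR)
}

#' Default per-factor resistance reclassification scheme
#'
#' Relative resistance values on a 1-500 scale for the six factors:
#' land use (vegetation 1, water 50, unused 200, construction 400, coal mine
#' 500, other 200), NDVI in six bands from 100 (negative) through 500 (bare)
#' down to 1 (dense cover), slope and DEM in five ascending bands
#' (100-500), and distance to road / mine in five descending bands (500 next
#' to the feature, 100 beyond 800 m). Numeric bands are half-open [lo, hi)
#' except the final NDVI band, which is closed at 1 so the domain is
#' covered. The `weights` component holds the AHP weights of
#' [default_judgment_matrix].
#'
#' @return named list with one entry per factor (`type` `"categorical"` with
#'   a code-value `map`, or `"bands"` with `lo`/`hi`/`value` vectors) plus a
#'   `weights` vector.
#' @export
default_resistance_scheme <- function() {
  codes <- landcover_codes()
  list(
    land_use = list(type = "categorical",
                    map = stats::setNames(c(50, 1, 400, 500, 200, 200),
                                          codes[c("water", "vegetation",
                                                  "construction", "coal_mine",
                                                  "unused", "other")])),
    ndvi = list(type = "bands", lo = c(-1, 0, 0.2, 0.4, 0.6, 0.8),
                hi = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                value = c(100, 500, 350, 250, 125, 1)),
    slope = list(type = "bands", lo = c(0, 5, 15, 25, 35),
                 hi = c(5, 15, 25, 35, 90),
                 value = c(100, 200, 300, 400, 500)),
    dem = list(type = "bands", lo = c(0, 300, 400, 500, 800),
               hi = c(300, 400, 500, 800, Inf),
               value = c(100, 200, 300, 400, 500)),
    dist_road = list(type = "bands", lo = c(0, 200, 400, 600, 800),
                     hi = c(200, 400, 600, 800, Inf),
                     value = c(500, 400, 300, 200, 100)),
    dist_mine = list(type = "bands", lo = c(0, 200, 400, 600, 800),
                     hi = c(200, 400, 600, 800, Inf),
                     value = c(500, 400, 300, 200, 100)),
    weights = ahp_weights(default_judgment_matrix())
  )
}

#' Reclassify a factor raster to resistance values
#'
#' Categorical factors are mapped code-by-code; numeric factors through
#' half-open bands [lo, hi), with the last band closed at its upper edge
#' when that edge is finite. Nodata propagates; a value outside every band
#' is an error naming the offending cell.
#'
#' @param raster factor `grid_raster`.
#' @param scheme one factor entry of a resistance scheme (see
#'   [default_resistance_scheme]).
#' @return resistance-valued [grid_raster].
#' @export
reclassify_factor <- function(raster, scheme) {
  stopifnot(is_grid_raster(raster))
  v <- raster$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  if (identical(scheme$type, "categorical")) {
    hit <- match(as.character(v[ok]), names(scheme$map))
    if (anyNA(hit)) {
      bad <- which(ok)[which(is.na(hit))[1]]
      rc <- arrayInd(bad, dim(v))
      stop(sprintf("value %g at cell (%d, %d) matches no class in the scheme",
                   v[bad], rc[1], rc[2]))
    }
    out[ok] <- scheme$map[hit]
  } else if (identical(scheme$type, "bands")) {
    brks <- c(scheme$lo, scheme$hi[length(scheme$hi)])
    band <- findInterval(v[ok], brks, rightmost.closed = is.finite(brks[length(brks)]))
    bad_i <- band < 1 | band > length(scheme$value)
    if (any(bad_i)) {
      bad <- which(ok)[which(bad_i)[1]]
      rc <- arrayInd(bad, dim(v))
      stop(sprintf("value %g at cell (%d, %d) lies outside all bands",
                   v[bad], rc[1], rc[2]))
    }
    out[ok] <- scheme$value[band]
  } else {
    stop("unknown scheme type: ", scheme$type)
  }
  grid_raster(out, raster$cell_size, raster$origin, raster$crs_tag,
              raster$nodata)
}

#' Weighted overlay of reclassified factor rasters
#'
#' R(cell) = sum_f w_f r_f(cell); any factor nodata makes the cell nodata.
#' With weights summing to 1 the surface is a convex combination bounded by
#' the per-factor resistance range.
#'
#' @param factors named list of aligned resistance-valued rasters.
#' @param weights named weights (names must cover the factors; order-free).
#' @return resistance-surface [grid_raster].
#' @export
weighted_overlay <- function(factors, weights) {
  if (!length(factors)) stop("no factor rasters supplied")
  if (is.null(names(factors)) || any(names(factors) == "")) {
    stop("`factors` must be a named list")
  }
  miss <- setdiff(names(factors), names(weights))
  if (length(miss)) stop("missing weight(s) for factor(s): ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(names(weights), names(factors))
  if (length(absent)) stop("missing factor raster(s): ",
                           paste(absent, collapse = ", "))
  check_alignment(factors)
  ref <- factors[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (nm in names(factors)) {
    acc <- acc + weights[[nm]] * factors[[nm]]$values
  }
  grid_raster(acc, ref$cell_size, ref$origin, ref$crs_tag, ref$nodata)
}
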