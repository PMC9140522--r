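#' MSPA class codes
#'
#' @return named integer vector: background 0, core 1, islet 2,
#'   perforation 3, edge 4, loop 5, bridge 6, branch 7.
#' @export
mspa_codes <- function() {
  c(background = 0L, core = 1L, islet = 2L, perforation = 3L, edge = 4L,
    loop = 5L, bridge = 6L, branch = 7L)
}

#' Ecological-land foreground mask
#'
#' Water bodies and vegetation are the ecological land ("foreground") for
#' the morphological segmentation; every other class is background.
#'
#' @param landcover categorical land-cover raster.
#' @return 0/1 [grid_raster].
#' @export
make_foreground <- function(landcover) {
  stopifnot(is_grid_raster(landcover))
  codes <- landcover_codes()
  fg <- !is.na(landcover$values) &
    landcover$values %in% codes[c("water", "vegetation")]
  grid_raster(fg, landcover$cell_size, landcover$origin, landcover$crs_tag,
              landcover$nodata)
}

# Chebyshev dilation of a logical matrix by s steps (3x3 square element);
# the raster border is treated as fixed `border` value
cheb_dilate <- function(mask, s) {
  for (k in seq_len(s)) {
    out <- mask
    for (o in neighbor_offsets()) {
      out <- out | shift_mat(mask, o[1], o[2], fill = FALSE)
    }
    mask <- out
  }
  mask
}

cheb_erode <- function(mask, s) {
  for (k in seq_len(s)) {
    out <- mask
    for (o in neighbor_offsets()) {
      out <- out & shift_mat(mask, o[1], o[2], fill = FALSE)
    }
    mask <- out
  }
  mask
}

# Euclidean distance (cells) to nearest TRUE cell; Inf if none.
# pad_open=TRUE treats the region outside the raster as TRUE (used for the
# open-background distance, since the world beyond the border is background).
euclid_dist_to <- function(mask, pad_open = FALSE) {
  if (!any(mask) && !pad_open) return(matrix(Inf, nrow(mask), ncol(mask)))
  if (pad_open) {
    nr <- nrow(mask); nc <- ncol(mask)
    m <- matrix(1, nr + 2, nc + 2)
    m[1, ] <- 0; m[nr + 2, ] <- 0; m[, 1] <- 0; m[, nc + 2] <- 0
    m[2:(nr + 1), 2:(nc + 1)][mask] <- 0
    d <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
    d[2:(nr + 1), 2:(nc + 1), drop = FALSE]
  } else {
    m <- matrix(1, nrow(mask), ncol(mask))
    m[mask] <- 0
    as.matrix(EBImage::distmap(m, metric = "euclidean"))
  }
}

#' Morphological spatial pattern analysis
#'
#' Segments a binary ecological-land raster into the seven MSPA classes with
#' 8-connected foreground, a square (Chebyshev) structuring element of
#' radius `edge_width`, and 4-connected background for the hole test:
#'
#' * **core** — foreground with Chebyshev distance to background (the raster
#'   border counts as background) greater than `edge_width`;
#' * **islet** — 8-connected foreground components containing no core;
#' * **perforation / edge** — the remaining cells within Chebyshev distance
#'   `edge_width` of core: perforation where the nearest background is an
#'   interior hole (a 4-connected background component not touching the
#'   border), edge otherwise;
#' * **bridge / loop / branch** — residual cells beyond the boundary band:
#'   bridge where the residual component contacts two or more distinct core
#'   components (through the band), loop where it contacts one core
#'   component at two or more disjoint interfaces, branch otherwise.
#'
#' @param foreground 0/1 (or logical) `grid_raster`; `NA` is background.
#' @param edge_width structuring-element radius s in cells (>= 1).
#' @return object of class `mspa_segmentation`: list with `classes` (coded
#'   [grid_raster]), `edge_width`, and `statistics` (see
#'   [class_statistics]).
#' @export
mspa_segment <- function(foreground, edge_width = 1) {
  stopifnot(is_grid_raster(foreground))
  s <- as.integer(edge_width)
  if (is.na(s) || s < 1) stop("`edge_width` must be a positive integer")
  fg <- !is.na(foreground$values) & foreground$values != 0
  nr <- nrow(fg); nc <- ncol(fg)
  cls <- matrix(mspa_codes()[["background"]], nr, nc)

  core <- cheb_erode(fg, s)
  comp_fg <- label_components(fg, conn = 8)
  core_comps <- unique(comp_fg[core])
  islet <- fg & !(comp_fg %in% core_comps)
  dim(islet) <- dim(fg)

  # boundary band: non-core, non-islet foreground within Chebyshev s of core,
  # labelled by the nearest core component (multi-source label dilation; ties
  # resolved to the smallest component label)
  core_lab <- label_components(core, conn = 8)
  assigned <- core_lab
  candidates <- fg & !core & !islet
  for (k in seq_len(s)) {
    best <- matrix(Inf, nr, nc)
    for (o in neighbor_offsets()) {
      v <- shift_mat(assigned, o[1], o[2], fill = 0L)
      v[v == 0] <- Inf
      best <- pmin(best, v)
    }
    new <- candidates & assigned == 0 & is.finite(best)
    assigned[new] <- as.integer(best[new])
  }
  band <- assigned > 0 & !core

  # perforation vs edge: nearest background component type
  bg <- !fg
  if (any(band)) {
    bg_lab <- label_components(bg, conn = 4)
    border_labs <- unique(c(bg_lab[1, ], bg_lab[nr, ], bg_lab[, 1], bg_lab[, nc]))
    border_labs <- border_labs[border_labs > 0]
    hole <- bg & !(bg_lab %in% border_labs)
    dim(hole) <- dim(fg)
    open_bg <- bg & !hole
    d_hole <- euclid_dist_to(hole)
    d_open <- euclid_dist_to(open_bg, pad_open = TRUE)
    perf <- band & (d_hole < d_open)   # ties go to edge
    cls[band & !perf] <- mspa_codes()[["edge"]]
    cls[perf] <- mspa_codes()[["perforation"]]
  }

  cls[core] <- mspa_codes()[["core"]]
  cls[islet] <- mspa_codes()[["islet"]]

  # residual connectors: bridge / loop / branch
  residual <- fg & !core & !islet & !band
  if (any(residual)) {
    res_lab <- label_components(residual, conn = 8)
    idx <- matrix(seq_len(nr * nc), nr, nc)
    pr <- integer(0); pc_ <- integer(0); pn <- integer(0)
    for (o in neighbor_offsets()) {
      alab <- shift_mat(assigned, o[1], o[2], fill = 0L)
      nidx <- shift_mat(idx, o[1], o[2], fill = 0L)
      sel <- res_lab > 0 & alab > 0
      if (any(sel)) {
        pr <- c(pr, res_lab[sel]); pc_ <- c(pc_, alab[sel])
        pn <- c(pn, nidx[sel])
      }
    }
    for (rid in sort(unique(res_lab[res_lab > 0]))) {
      touch <- pr == rid
      cores_hit <- unique(pc_[touch])
      cells <- res_lab == rid
      if (length(cores_hit) >= 2) {
        cls[cells] <- mspa_codes()[["bridge"]]
      } else if (length(cores_hit) == 1) {
        # disjoint interfaces: cluster the contacted band/core cells
        contact <- matrix(FALSE, nr, nc)
        contact[unique(pn[touch])] <- TRUE
        n_ifc <- max(label_components(contact, conn = 8))
        cls[cells] <- if (n_ifc >= 2) mspa_codes()[["loop"]]
                      else mspa_codes()[["branch"]]
      } else {
        cls[cells] <- mspa_codes()[["branch"]]
      }
    }
  }

  classes <- grid_raster(cls, foreground$cell_size, foreground$origin,
                         foreground$crs_tag, foreground$nodata)
  out <- structure(list(classes = classes, edge_width = s),
                   class = "mspa_segmentation")
  out$statistics <- class_statistics(out)
  out
}

#' @export
print.mspa_segmentation <- function(x, ...) {
  cat(sprintf("<mspa_segmentation> edge width %d cell(s)\n", x$edge_width))
  print(x$statistics, row.names = FALSE)
  invisible(x)
}

#' Per-class area statistics of an MSPA segmentation
#'
#' Areas in hectares (cell count x cell_size^2 / 1e4) and percentages of the
#' total ecological land (foreground). With an empty foreground all values
#' are zero and the result carries attribute `empty_foreground = TRUE`.
#'
#' @param segmentation an `mspa_segmentation`.
#' @param cell_size cell size in metres (defaults to the segmentation's).
#' @return data.frame with columns `class`, `code`, `cells`, `area_ha`,
#'   `pct_ecological_land`.
#' @export
class_statistics <- function(segmentation, cell_size = NULL) {
  stopifnot(inherits(segmentation, "mspa_segmentation"))
  if (is.null(cell_size)) cell_size <- segmentation$classes$cell_size
  cls <- segmentation$classes$values
  codes <- mspa_codes()
  fg_codes <- codes[names(codes) != "background"]
  counts <- vapply(fg_codes, function(k) sum(cls == k, na.rm = TRUE), numeric(1))
  total <- sum(counts)
  out <- data.frame(class = names(fg_codes), code = as.integer(fg_codes),
                    cells = as.integer(counts),
                    area_ha = counts * cell_size^2 / 1e4,
                    pct_ecological_land = if (total > 0) 100 * counts / total
                                          else rep(0, length(counts)),
                    row.names = NULL)
  if (total == 0) attr(out, "empty_foreground") <- TRUE
  out
}
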