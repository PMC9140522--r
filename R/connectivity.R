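#' Extract habitat patches from an MSPA segmentation
#'
#' Patches are the 8-connected components of the core class; areas are in
#' hectares. An empty core yields an empty list.
#'
#' @param segmentation an `mspa_segmentation` (or a coded class raster).
#' @param cell_size cell size in metres (defaults to the raster's).
#' @return list of patches, each a list with `id`, `cells` (two-column
#'   row/col matrix) and `area_ha`; carries attribute `cell_size`.
#' @export
extract_patches <- function(segmentation, cell_size = NULL) {
  cls <- if (inherits(segmentation, "mspa_segmentation")) segmentation$classes
         else segmentation
  stopifnot(is_grid_raster(cls))
  if (is.null(cell_size)) cell_size <- cls$cell_size
  core <- !is.na(cls$values) & cls$values == mspa_codes()[["core"]]
  lab <- label_components(core, conn = 8)
  k <- max(lab)
  patches <- vector("list", k)
  for (i in seq_len(k)) {
    cells <- which(lab == i, arr.ind = TRUE)
    colnames(cells) <- c("row", "col")
    patches[[i]] <- list(id = i, cells = cells,
                         area_ha = nrow(cells) * cell_size^2 / 1e4)
  }
  attr(patches, "cell_size") <- cell_size
  patches
}

# boundary cells of a patch (any 8-neighbour outside the patch); the minimum
# inter-patch distance is always attained between boundary cells
patch_boundary <- function(cells) {
  if (nrow(cells) <= 8) return(cells)
  rmin <- min(cells[, 1]); cmin <- min(cells[, 2])
  m <- matrix(FALSE, max(cells[, 1]) - rmin + 3, max(cells[, 2]) - cmin + 3)
  m[cbind(cells[, 1] - rmin + 2, cells[, 2] - cmin + 2)] <- TRUE
  interior <- cheb_erode(m, 1)
  keep <- !interior[cbind(cells[, 1] - rmin + 2, cells[, 2] - cmin + 2)]
  cells[keep, , drop = FALSE]
}

#' Edge-to-edge distances between patches
#'
#' Minimum cell-centre to cell-centre Euclidean distance over all pairs of
#' cells of the two patches, in metres; zero on the diagonal.
#'
#' @param patches list from [extract_patches].
#' @param cell_size metres per cell (defaults to the list's attribute).
#' @return symmetric numeric matrix.
#' @export
patch_distances <- function(patches, cell_size = NULL) {
  if (is.null(cell_size)) cell_size <- attr(patches, "cell_size")
  if (is.null(cell_size)) stop("`cell_size` required")
  n <- length(patches)
  if (n == 0) stop("at least one patch required")
  d <- matrix(0, n, n)
  bnd <- lapply(patches, function(p) patch_boundary(p$cells))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- bnd[[i]]; b <- bnd[[j]]
      dr <- outer(a[, 1], b[, 1], "-")
      dc <- outer(a[, 2], b[, 2], "-")
      d[i, j] <- d[j, i] <- sqrt(min(dr * dr + dc * dc)) * cell_size
    }
  }
  d
}

#' Habitat patch graph
#'
#' Holds the patch areas, pairwise edge-to-edge distances, the binary link
#' set (pairs within `d_threshold`), topological link counts `nl_ij`
#' (shortest path in links, used by IIC), and the maximum-product dispersal
#' probabilities `p_star_ij` (used by PC) under the negative-exponential
#' kernel `p_ij = p_threshold^(d_ij / d_threshold)` anchored so that a pair
#' exactly `d_threshold` apart disperses with probability `p_threshold`.
#'
#' @param patches list from [extract_patches].
#' @param AL total landscape area in hectares.
#' @param cell_size metres per cell.
#' @param d_threshold link distance threshold in metres (default 500).
#' @param p_threshold dispersal probability at `d_threshold` (default 0.5).
#' @param dist optional precomputed distance matrix (used internally by the
#'   leave-one-out removal so distances stay fixed among survivors).
#' @return object of class `patch_graph`.
#' @export
patch_graph <- function(patches, AL, cell_size = NULL, d_threshold = 500,
                        p_threshold = 0.5, dist = NULL) {
  if (!is.numeric(AL) || AL <= 0) stop("`AL` (landscape area, ha) must be > 0")
  if (d_threshold <= 0) stop("`d_threshold` must be > 0")
  if (p_threshold <= 0 || p_threshold >= 1) stop("`p_threshold` must be in (0, 1)")
  n <- length(patches)
  if (is.null(dist)) {
    dist <- if (n > 0) patch_distances(patches, cell_size) else
      matrix(0, 0, 0)
  }
  areas <- vapply(patches, function(p) p$area_ha, numeric(1))
  nl <- matrix(Inf, n, n)
  p_star <- matrix(0, n, n)
  if (n > 0) {
    links <- dist <= d_threshold
    diag(links) <- FALSE
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    lp <- which(links & upper.tri(links), arr.ind = TRUE)
    if (nrow(lp)) g <- igraph::add_edges(g, rbind(lp[, 1], lp[, 2]))
    nl <- igraph::distances(g)          # unweighted hop counts, Inf if disconnected
    # maximum-product path probabilities: shortest paths on -log p over the
    # complete kernel graph (multi-hop routes can beat the direct kernel
    # because edge-to-edge distances need not satisfy the triangle inequality)
    p_direct <- p_threshold^(dist / d_threshold)
    if (n > 1) {
      gw <- igraph::make_empty_graph(n = n, directed = FALSE)
      up <- which(upper.tri(dist), arr.ind = TRUE)
      gw <- igraph::add_edges(gw, rbind(up[, 1], up[, 2]),
                              weight = -log(p_direct[up]))
      p_star <- exp(-igraph::distances(gw))
    }
    diag(p_star) <- 1
  }
  structure(list(patches = patches, areas = areas, AL = AL, dist = dist,
                 d_threshold = d_threshold, p_threshold = p_threshold,
                 nl = nl, p_star = p_star),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d patches, AL = %.4g ha, threshold %g m (p = %g)\n",
              length(x$patches), x$AL, x$d_threshold, x$p_threshold))
  cat(sprintf("  IIC = %.6g, PC = %.6g\n", iic(x), pc(x)))
  invisible(x)
}

#' Integral index of connectivity
#'
#' IIC = [sum_i sum_j a_i a_j / (1 + nl_ij)] / AL^2 over all ordered pairs
#' including i = j (nl_ii = 0); pairs in different components contribute 0.
#'
#' @param graph a [patch_graph].
#' @return IIC in [0, 1]; 0 for an empty graph.
#' @export
iic <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  n <- length(graph$areas)
  if (n == 0) return(0)
  M <- outer(graph$areas, graph$areas) / (1 + graph$nl)
  sum(M) / graph$AL^2
}

#' Probability of connectivity
#'
#' PC = [sum_i sum_j a_i a_j p*_ij] / AL^2 with p*_ij the maximum-product
#' dispersal probability between patches i and j (p*_ii = 1).
#'
#' @param graph a [patch_graph].
#' @return PC in [0, 1]; 0 for an empty graph.
#' @export
pc <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  n <- length(graph$areas)
  if (n == 0) return(0)
  sum(outer(graph$areas, graph$areas) * graph$p_star) / graph$AL^2
}

#' Per-patch importance by leave-one-out removal
#'
#' dI_k = 100 (I - I_remove(k)) / I, where I_remove(k) recomputes the index
#' on the graph without patch k; distances among the survivors are unchanged.
#'
#' @param graph a [patch_graph].
#' @param index `"PC"` or `"IIC"`.
#' @return numeric vector of dPC (or dIIC) values, one per patch.
#' @export
delta_importance <- function(graph, index = c("PC", "IIC")) {
  stopifnot(inherits(graph, "patch_graph"))
  index <- match.arg(index)
  f <- if (index == "PC") pc else iic
  I_full <- f(graph)
  if (I_full <= 0) stop("full-graph ", index, " is zero; importance undefined")
  n <- length(graph$patches)
  vapply(seq_len(n), function(k) {
    keep <- setdiff(seq_len(n), k)
    sub <- patch_graph(graph$patches[keep], graph$AL,
                       d_threshold = graph$d_threshold,
                       p_threshold = graph$p_threshold,
                       dist = graph$dist[keep, keep, drop = FALSE])
    100 * (I_full - f(sub)) / I_full
  }, numeric(1))
}

#' Patch importance ranking table
#'
#' dIIC and dPC for every patch with its area, sorted by decreasing dPC
#' (ties by larger area, then lower id).
#'
#' @param graph a [patch_graph].
#' @return data.frame with columns `patch`, `dIIC`, `dPC`, `area_ha`.
#' @export
connectivity_ranking <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  d_iic <- delta_importance(graph, "IIC")
  d_pc <- delta_importance(graph, "PC")
  out <- data.frame(patch = vapply(graph$patches, `[[`, numeric(1), "id"),
                    dIIC = d_iic, dPC = d_pc, area_ha = graph$areas)
  out[order(-out$dPC, -out$area_ha, out$patch), , drop = FALSE]
}

#' Select ecological sources
#'
#' The k patches with the largest dPC, ties broken by larger area then lower
#' patch id. If fewer than k patches exist all are returned with a warning.
#'
#' @param patches list from [extract_patches].
#' @param dpc per-patch dPC values aligned with `patches`.
#' @param k number of sources to keep (default 10).
#' @return the selected patches (same structure as `patches`), with the
#'   ranking stored in attribute `ranking`.
#' @export
select_sources <- function(patches, dpc, k = 10) {
  n <- length(patches)
  if (n == 0) stop("no ecological sources: patch list is empty")
  if (length(dpc) != n) stop("`dpc` must have one value per patch")
  areas <- vapply(patches, function(p) p$area_ha, numeric(1))
  ids <- vapply(patches, function(p) p$id, numeric(1))
  ord <- order(-dpc, -areas, ids)
  if (n < k) {
    warning("only ", n, " patches available; returning all of them")
    k <- n
  }
  sel <- ord[seq_len(k)]
  out <- patches[sel]
  attr(out, "cell_size") <- attr(patches, "cell_size")
  attr(out, "ranking") <- data.frame(patch = ids[sel], dPC = dpc[sel],
                                     area_ha = areas[sel])
  out
}
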