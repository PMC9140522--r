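# Move cost between 8-adjacent cells a, b: (R_a + R_b)/2 * L with L = 1 for
# orthogonal and sqrt(2) for diagonal steps (cell units) — the standard GIS
# cost-distance convention for the minimum-cumulative-resistance model.

# build the undirected 8-neighbour lattice over traversable cells
grid_cost_graph <- function(R) {
  nr <- nrow(R); nc <- ncol(R)
  ok <- !is.na(R) & R > 0
  idx <- matrix(seq_len(nr * nc), nr, nc)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  dirs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))
  for (d in dirs) {
    dr <- d[[1]]; dc <- d[[2]]; L <- d[[3]]
    if (nr - dr < 1 || nc - abs(dc) < 1) next
    rs <- if (dr > 0) 1:(nr - dr) else 1:nr
    cs <- if (dc > 0) 1:(nc - dc) else if (dc < 0) (1 - dc):nc else 1:nc
    a <- idx[rs, cs, drop = FALSE]
    b <- idx[rs + dr, cs + dc, drop = FALSE]
    keep <- ok[a] & ok[b]
    from <- c(from, a[keep]); to <- c(to, b[keep])
    w <- c(w, (R[a[keep]] + R[b[keep]]) / 2 * L)
  }
  list(n = nr * nc, from = from, to = to, w = w, ok = ok)
}

as_cell_index <- function(cells, raster) {
  nr <- nrow(raster$values)
  if (is_grid_raster(cells)) {
    check_alignment(cells, raster)
    which(!is.na(cells$values) & cells$values != 0)
  } else if (is.matrix(cells) && ncol(cells) == 2) {
    lin_index(cells[, 1], cells[, 2], nr)
  } else {
    as.integer(cells)
  }
}

#' Cost distance over a resistance surface
#'
#' Multi-source Dijkstra on the 8-neighbour lattice, with move cost
#' (R_a + R_b)/2 between orthogonal neighbours and sqrt(2) times that
#' between diagonal neighbours (cell units). Accumulated cost is 0 on
#' source cells; nodata (and non-positive) resistance cells are impassable.
#' The backlink raster encodes, for every reached cell, the direction of its
#' predecessor on an optimal path (1-8 in the clockwise scan order E, SE, S,
#' SW, W, NW, N, NE; 0 marks sources, NA unreached cells).
#'
#' @param resistance resistance `grid_raster` (values > 0 traversable).
#' @param sources source cells: a 0/1 raster, a two-column row/col matrix,
#'   or linear cell indices.
#' @return object of class `cost_distance`: list with `accumulated`
#'   ([grid_raster]), `backlink` (integer matrix) and `sources` (indices).
#' @export
cost_distance <- function(resistance, sources) {
  stopifnot(is_grid_raster(resistance))
  R <- resistance$values
  nr <- nrow(R); nc <- ncol(R)
  src <- as_cell_index(sources, resistance)
  if (!length(src)) stop("no source cells given")
  gg <- grid_cost_graph(R)
  src <- src[gg$ok[src]]
  if (!length(src)) stop("all source cells fall on impassable (nodata) cells")
  # virtual super-source with zero-cost edges to every source cell
  v0 <- gg$n + 1L
  g <- igraph::make_empty_graph(n = v0, directed = FALSE)
  g <- igraph::add_edges(g, rbind(c(gg$from, rep(v0, length(src))),
                                  c(gg$to, src)),
                         weight = c(gg$w, rep(0, length(src))))
  acc <- as.numeric(igraph::distances(g, v = v0))[seq_len(gg$n)]
  acc_m <- matrix(acc, nr, nc)
  acc_m[!gg$ok] <- NA

  # backlink: first neighbour (fixed clockwise order from east) that attains
  # acc[cell] = acc[nb] + movecost(nb, cell)
  backlink <- matrix(NA_integer_, nr, nc)
  reached <- is.finite(acc_m)
  backlink[reached] <- -1L
  backlink[src] <- 0L
  offs <- neighbor_offsets()
  tol <- 1e-9
  pend <- reached
  pend[src] <- FALSE
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    L <- if (o[1] != 0 && o[2] != 0) sqrt(2) else 1
    acc_nb <- shift_mat(acc_m, o[1], o[2], fill = Inf)
    R_nb <- shift_mat(R, o[1], o[2], fill = NA)
    cand <- acc_nb + (R + R_nb) / 2 * L
    hit <- pend & is.finite(cand) &
      abs(cand - acc_m) <= tol * pmax(1, abs(acc_m))
    hit[is.na(hit)] <- FALSE
    backlink[hit] <- k
    pend <- pend & !hit
  }
  structure(list(
    accumulated = grid_raster(acc_m, resistance$cell_size, resistance$origin,
                              resistance$crs_tag, resistance$nodata),
    backlink = backlink, sources = src),
    class = "cost_distance")
}

#' Trace the least-cost path to a destination
#'
#' Picks the destination cell with the minimum accumulated cost (ties to the
#' lowest linear index) and walks the backlink raster to a source; the path
#' is returned running source to destination.
#'
#' @param cd a [cost_distance] result.
#' @param destination destination cells (raster / row-col matrix / indices).
#' @return list with `cells` (row/col matrix, source first), `cost`
#'   (accumulated cost at the destination) and `length_km` (geometric path
#'   length).
#' @export
least_cost_path <- function(cd, destination) {
  stopifnot(inherits(cd, "cost_distance"))
  acc <- cd$accumulated$values
  nr <- nrow(acc)
  dst <- as_cell_index(destination, cd$accumulated)
  if (!length(dst)) stop("no destination cells given")
  vals <- acc[dst]
  if (all(!is.finite(vals) | is.na(vals))) {
    stop("destination unreachable from the sources (disconnected pair)")
  }
  best <- dst[order(vals, dst)][1]
  offs <- neighbor_offsets()
  path <- integer(0)
  cur <- best
  repeat {
    path <- c(path, cur)
    bl <- cd$backlink[cur]
    if (is.na(bl) || bl < 0) stop("broken backlink at cell ", cur)
    if (bl == 0L) break
    o <- offs[[bl]]
    rc <- arrayInd(cur, dim(acc))
    cur <- lin_index(rc[1] + o[1], rc[2] + o[2], nr)
  }
  path <- rev(path)
  rc <- arrayInd(path, dim(acc))
  colnames(rc) <- c("row", "col")
  steps <- diff(rc)
  len <- if (nrow(rc) > 1) {
    sum(ifelse(abs(steps[, 1]) + abs(steps[, 2]) == 2, sqrt(2), 1))
  } else 0
  list(cells = rc, cost = acc[best],
       length_km = len * cd$accumulated$cell_size / 1000)
}

#' Build ecological corridors between source patches
#'
#' Computes the least-cost path for every unordered pair of source patches
#' (each pair treating one patch's cells as the multi-source set and the
#' other's as destinations), then prunes redundancy: raw paths are processed
#' in ascending cost order and a path is discarded when more than
#' `prune_overlap` of its cells already lie in the union of retained paths
#' or inside source patches. Disconnected pairs are skipped with a warning.
#'
#' @param sources list of >= 2 source patches (see [select_sources]).
#' @param resistance resistance `grid_raster`.
#' @param prune_overlap overlap fraction above which a path is redundant
#'   (default 0.8; a value > 1 disables pruning).
#' @return object of class `corridor_set`: data.frame `corridors`
#'   (`from`, `to`, `cost`, `length_km`, `retained`), list `paths` of cell
#'   matrices, list `accumulated` of per-source cost rasters, plus
#'   `n_corridors` and `total_length_km` for the retained set.
#' @export
build_corridors <- function(sources, resistance, prune_overlap = 0.8) {
  k <- length(sources)
  if (k < 2) stop("at least two source patches are required")
  nr <- nrow(resistance$values)
  patch_idx <- lapply(sources, function(p) lin_index(p$cells[, 1], p$cells[, 2], nr))
  acc_list <- vector("list", k - 1)
  rows <- list(); paths <- list()
  key <- 0L
  for (i in seq_len(k - 1)) {
    cd <- cost_distance(resistance, patch_idx[[i]])
    acc_list[[i]] <- cd$accumulated
    for (j in (i + 1):k) {
      res <- tryCatch(least_cost_path(cd, patch_idx[[j]]), error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("source pair (%d, %d) disconnected; skipped",
                        sources[[i]]$id, sources[[j]]$id))
        next
      }
      key <- key + 1L
      rows[[key]] <- data.frame(from = sources[[i]]$id, to = sources[[j]]$id,
                                cost = res$cost, length_km = res$length_km)
      paths[[key]] <- res$cells
    }
  }
  if (!key) stop("no connected source pairs")
  tab <- do.call(rbind, rows)
  ord <- order(tab$cost, tab$from, tab$to)
  tab <- tab[ord, , drop = FALSE]
  paths <- paths[ord]
  union_cells <- unique(unlist(patch_idx))
  retained <- logical(nrow(tab))
  for (m in seq_len(nrow(tab))) {
    pcells <- lin_index(paths[[m]][, 1], paths[[m]][, 2], nr)
    overlap <- mean(pcells %in% union_cells)
    if (overlap <= prune_overlap) {
      retained[m] <- TRUE
      union_cells <- unique(c(union_cells, pcells))
    }
  }
  tab$retained <- retained
  structure(list(corridors = tab, paths = paths, accumulated = acc_list,
                 n_corridors = sum(retained),
                 total_length_km = sum(tab$length_km[retained]),
                 prune_overlap = prune_overlap,
                 cell_size = resistance$cell_size,
                 origin = resistance$origin),
            class = "corridor_set")
}

#' @export
print.corridor_set <- function(x, ...) {
  cat(sprintf("<corridor_set> %d retained of %d raw corridors, total %.3f km\n",
              x$n_corridors, nrow(x$corridors), x$total_length_km))
  print(utils::head(x$corridors, 10), row.names = FALSE)
  invisible(x)
}

#' Extract ridgelines from a DEM
#'
#' D8 flow routing: each cell drains to the steepest-descent neighbour of
#' its eight (drop divided by 1 or sqrt(2); ties resolved to the first
#' direction in the fixed clockwise order starting east). Flow accumulation
#' counts the cells draining through each cell; ridge cells are those with
#' zero accumulation (no cell drains into them). Single-cell pits are left
#' as local sinks: they still receive their neighbours' flow, so they are
#' never spurious ridges (raising them to their lowest neighbour would
#' flatten the inflow and mark every enclosed minimum as a ridge). A
#' perfectly flat DEM has no flow at all, so every cell is a ridge cell;
#' this degenerate case raises a warning.
#'
#' @param dem elevation `grid_raster`.
#' @return 0/1 ridge [grid_raster] with attributes `accumulation` and
#'   `receiver` (linear index of the downstream cell, NA where flow stops).
#' @export
extract_ridgelines <- function(dem) {
  stopifnot(is_grid_raster(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  offs <- neighbor_offsets()
  best_drop <- matrix(0, nr, nc)
  receiver <- matrix(NA_integer_, nr, nc)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    L <- if (o[1] != 0 && o[2] != 0) sqrt(2) else 1
    z_nb <- shift_mat(z, o[1], o[2], fill = NA)
    i_nb <- shift_mat(idx, o[1], o[2], fill = NA)
    drop <- (z - z_nb) / L
    better <- !is.na(drop) & drop > best_drop   # strict: first direction wins ties
    best_drop[better] <- drop[better]
    receiver[better] <- i_nb[better]
  }
  if (all(is.na(receiver[!is.na(z)])) && any(!is.na(z))) {
    warning("flat DEM: no flow directions; every cell is a ridge cell")
  }
  acc <- numeric(nr * nc)
  ord <- order(-as.vector(z), seq_len(nr * nc), na.last = TRUE)
  for (cell in ord) {
    rcv <- receiver[cell]
    if (!is.na(rcv)) acc[rcv] <- acc[rcv] + acc[cell] + 1
  }
  acc_m <- matrix(acc, nr, nc)
  ridge <- acc_m == 0 & !is.na(z)
  out <- grid_raster(ridge, dem$cell_size, dem$origin, dem$crs_tag, dem$nodata)
  attr(out, "accumulation") <- acc_m
  attr(out, "receiver") <- receiver
  out
}

#' Identify ecological nodes
#'
#' Candidate nodes are corridor path cells that are also ridge cells
#' (optionally plus corridor-corridor crossing cells); candidates within
#' `merge_radius` (Chebyshev, cells) of one another are merged to their
#' centroid cell.
#'
#' @param corridors a [build_corridors] result.
#' @param ridge ridge raster from [extract_ridgelines].
#' @param merge_radius merge radius in cells (default 3).
#' @param include_crossings also treat cells shared by two or more retained
#'   corridors as candidates (default `FALSE`).
#' @return object of class `node_set`: data.frame with node row/col, world
#'   x/y, number of merged candidates and the contributing corridor ids.
#' @export
identify_nodes <- function(corridors, ridge, merge_radius = 3,
                           include_crossings = FALSE) {
  stopifnot(inherits(corridors, "corridor_set"), is_grid_raster(ridge))
  nr <- nrow(ridge$values)
  keep <- which(corridors$corridors$retained)
  cand_cells <- integer(0); cand_cor <- integer(0)
  for (m in keep) {
    cells <- unique(lin_index(corridors$paths[[m]][, 1],
                              corridors$paths[[m]][, 2], nr))
    on_ridge <- cells[!is.na(ridge$values[cells]) & ridge$values[cells] != 0]
    cand_cells <- c(cand_cells, on_ridge)
    cand_cor <- c(cand_cor, rep(m, length(on_ridge)))
  }
  if (include_crossings && length(keep) > 1) {
    all_cells <- unlist(lapply(keep, function(m)
      unique(lin_index(corridors$paths[[m]][, 1], corridors$paths[[m]][, 2], nr))))
    cross <- unique(all_cells[duplicated(all_cells)])
    cand_cells <- c(cand_cells, cross)
    cand_cor <- c(cand_cor, rep(NA_integer_, length(cross)))
  }
  empty <- data.frame(node = integer(0), row = integer(0), col = integer(0),
                      x = numeric(0), y = numeric(0),
                      n_candidates = integer(0), corridors = character(0))
  if (!length(cand_cells)) {
    return(structure(empty, class = c("node_set", "data.frame")))
  }
  o <- order(cand_cells)
  cand_cells <- cand_cells[o]; cand_cor <- cand_cor[o]
  uc <- !duplicated(cand_cells)
  rc <- arrayInd(cand_cells, dim(ridge$values))
  # cluster candidates within the Chebyshev merge radius
  ucells <- cand_cells[uc]
  urc <- rc[uc, , drop = FALSE]
  m <- length(ucells)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (m > 1) {
    pairs <- which(outer(urc[, 1], urc[, 1], function(a, b) abs(a - b)) <= merge_radius &
                   outer(urc[, 2], urc[, 2], function(a, b) abs(a - b)) <= merge_radius,
                   arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]))
  }
  memb <- igraph::components(g)$membership
  nodes <- lapply(sort(unique(memb)), function(cl) {
    sel <- memb == cl
    crow <- round(mean(urc[sel, 1])); ccol <- round(mean(urc[sel, 2]))
    cors <- sort(unique(cand_cor[cand_cells %in% ucells[sel]]))
    xy <- cell_center_xy(ridge, crow, ccol)
    data.frame(node = cl, row = crow, col = ccol, x = xy[1], y = xy[2],
               n_candidates = sum(sel),
               corridors = paste(cors[!is.na(cors)], collapse = ","))
  })
  out <- do.call(rbind, nodes)
  out$node <- seq_len(nrow(out))
  structure(out, class = c("node_set", "data.frame"))
}
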