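# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph): plain-R brute force only.

# brute-force Euclidean distance transform (cell units)
oracle_distance <- function(feature_mask) {
  nr <- nrow(feature_mask); nc <- ncol(feature_mask)
  ij <- which(feature_mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      out[r, cl] <- sqrt(min((ij[, 1] - r)^2 + (ij[, 2] - cl)^2))
    }
  }
  out
}

# Horn slope at one interior cell, straight from the stencil definition
oracle_horn_cell <- function(z, r, cl, cs) {
  a <- z[r - 1, cl - 1]; b <- z[r - 1, cl]; cc <- z[r - 1, cl + 1]
  d <- z[r, cl - 1];                         f <- z[r, cl + 1]
  g <- z[r + 1, cl - 1]; h <- z[r + 1, cl]; i <- z[r + 1, cl + 1]
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  gy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

# recursive flood-fill component count (8-connectivity)
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (mask[r0, c0] && !seen[r0, c0]) {
      n <- n + 1
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; cl <- p[2] + dc
          if (r >= 1 && r <= nr && cl >= 1 && cl <= nc &&
              mask[r, cl] && !seen[r, cl]) {
            seen[r, cl] <- TRUE
            stack[[length(stack) + 1]] <- c(r, cl)
          }
        }
      }
    }
  }
  n
}

# exhaustive minimum pairwise cell distance between two patches
oracle_patch_dist <- function(a, b, cell_size) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    best <- min(best, sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2))
  }
  best * cell_size
}

# Floyd-Warshall hop counts over a link adjacency matrix
oracle_hops <- function(links) {
  n <- nrow(links)
  d <- matrix(Inf, n, n)
  d[links] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# maximum-product dispersal probability by exhaustive simple-path enumeration
oracle_pstar <- function(p_direct) {
  n <- nrow(p_direct)
  best <- diag(1, n)
  explore <- function(path, prob, target) {
    cur <- path[length(path)]
    if (cur == target) {
      if (prob > best[path[1], target]) {
        best[path[1], target] <<- prob
      }
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!(nxt %in% path)) {
        explore(c(path, nxt), prob * p_direct[cur, nxt], target)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) explore(i, 1, j)
  }
  best
}

oracle_iic <- function(areas, nl, AL) {
  sum(outer(areas, areas) / (1 + nl)) / AL^2
}

oracle_pc <- function(areas, p_star, AL) {
  sum(outer(areas, areas) * p_star) / AL^2
}

# a random synthetic patch graph: areas and a random symmetric distance matrix
random_patch_graph_inputs <- function(n, d_max = 1500) {
  areas <- round(runif(n, 1, 50), 2)
  d <- matrix(0, n, n)
  up <- upper.tri(d)
  d[up] <- runif(sum(up), 10, d_max)
  d <- d + t(d)
  patches <- lapply(seq_len(n), function(i)
    list(id = i, cells = cbind(row = i, col = 1), area_ha = areas[i]))
  list(patches = patches, areas = areas, dist = d)
}

# Bellman-Ford accumulated costs on the 8-neighbour lattice with
# average-resistance move costs; iterative relaxation in plain R
oracle_cost_distance <- function(R, src_idx) {
  nr <- nrow(R); nc <- ncol(R)
  acc <- matrix(Inf, nr, nc)
  acc[src_idx] <- 0
  moves <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1),
                c(0, -1), c(-1, 0), c(-1, -1), c(-1, 1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if (is.na(R[r, cl])) next
      for (mv in moves) {
        r2 <- r + mv[1]; c2 <- cl + mv[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(R[r2, c2])) next
        L <- if (mv[1] != 0 && mv[2] != 0) sqrt(2) else 1
        cand <- acc[r2, c2] + (R[r, cl] + R[r2, c2]) / 2 * L
        if (cand < acc[r, cl] - 1e-12) { acc[r, cl] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  acc
}

# D8 receiver + accumulation traced cell by cell from the definition
oracle_d8 <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  recv <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    best <- 0; arg <- NA_integer_
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cl + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      L <- if (o[1] != 0 && o[2] != 0) sqrt(2) else 1
      drop <- (z[r, cl] - z[r2, c2]) / L
      if (drop > best) { best <- drop; arg <- (c2 - 1) * nr + r2 }
    }
    recv[r, cl] <- arg
  }
  acc <- matrix(0, nr, nc)
  ord <- order(-as.vector(z))
  for (cell in ord) {
    if (!is.na(recv[cell])) acc[recv[cell]] <- acc[recv[cell]] + acc[cell] + 1
  }
  list(receiver = recv, accumulation = acc)
}

mk_raster <- function(m, cell_size = 10) grid_raster(m, cell_size = cell_size)
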