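# Independent oracles the implementation is checked against. Deliberately
# naive and written without igraph/Matrix: Bellman-Ford relaxation, exhaustive
# path enumeration, and dense linear algebra with base::solve().

# edge list of a grid of resistances (mirrors the package's move model:
# cost = mean resistance x centre distance, sqrt(2) on diagonals)
oracle_edges <- function(res, cell_size = 30, neighbors = 8) {
  nr <- nrow(res); nc <- ncol(res)
  steps <- list(c(0, 1, 1), c(1, 0, 1))
  if (neighbors == 8) steps <- c(steps, list(c(1, 1, sqrt(2)), c(1, -1, sqrt(2))))
  out <- NULL
  for (r in seq_len(nr)) for (c2 in seq_len(nc)) {
    if (!is.finite(res[r, c2])) next
    for (s in steps) {
      r2 <- r + s[1]; c3 <- c2 + s[2]
      if (r2 < 1 || r2 > nr || c3 < 1 || c3 > nc) next
      if (!is.finite(res[r2, c3])) next
      w <- (res[r, c2] + res[r2, c3]) / 2 * cell_size * s[3]
      out <- rbind(out, c(r + (c2 - 1) * nr, r2 + (c3 - 1) * nr, w))
    }
  }
  out
}

# single-source shortest distances by Bellman-Ford relaxation to fixpoint
oracle_bellman_ford <- function(res, src_idx, cell_size = 30, neighbors = 8) {
  e <- oracle_edges(res, cell_size, neighbors)
  n <- length(res)
  d <- rep(Inf, n)
  d[src_idx] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      a <- e[k, 1]; b <- e[k, 2]; w <- e[k, 3]
      if (d[a] + w < d[b]) { d[b] <- d[a] + w; changed <- TRUE }
      if (d[b] + w < d[a]) { d[a] <- d[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# exhaustive minimum cost over all simple paths (tiny grids only)
oracle_enumerate_cost <- function(res, src_idx, tgt_idx, cell_size = 30,
                                  neighbors = 8) {
  e <- oracle_edges(res, cell_size, neighbors)
  n <- length(res)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], e[k, 2:3])
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], e[k, 3]))
  }
  best <- Inf
  visit <- function(v, cost, seen) {
    if (cost >= best) return()
    if (v == tgt_idx) { best <<- cost; return() }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      if (!seen[nb[k, 1]]) {
        seen[nb[k, 1]] <- TRUE
        visit(nb[k, 1], cost + nb[k, 2], seen)
        seen[nb[k, 1]] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n); seen[src_idx] <- TRUE
  visit(src_idx, 0, seen)
  best
}

# node voltages for 1 A injected at s, drawn at t, by dense solve of the
# Kirchhoff system (ground = t at 0 V); res: resistance matrix, 4/8-neighbour
oracle_circuit_voltages <- function(res, s, t, cell_size = 30, neighbors = 8) {
  e <- oracle_edges(res, cell_size, neighbors)
  n <- length(res)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]; g <- 1 / e[k, 3]
    L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
    L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
  }
  b <- rep(0, n); b[s] <- 1; b[t] <- -1
  v <- rep(0, n)
  keep <- setdiff(seq_len(n), t)
  v[keep] <- solve(L[keep, keep], b[keep])
  v
}

# all simple paths between two nodes of a complete graph over n nodes
oracle_max_product <- function(p, i, j) {
  n <- nrow(p)
  best <- p[i, j]
  visit <- function(v, prob, seen) {
    if (v == j) { best <<- max(best, prob); return() }
    for (w in seq_len(n)) {
      if (!seen[w] && is.finite(p[v, w]) && p[v, w] > 0) {
        seen[w] <- TRUE
        visit(w, prob * p[v, w], seen)
        seen[w] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n); seen[i] <- TRUE; seen[j] <- FALSE
  visit(i, 1, seen)
  best
}

# PC by direct double sum with enumerated max-product probabilities
oracle_pc <- function(areas, p, A_L) {
  n <- length(areas)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ps <- if (i == j) 1 else oracle_max_product(p, i, j)
    tot <- tot + areas[i] * areas[j] * ps
  }
  tot / A_L^2
}

# build a patch_graph by hand from areas and a distance matrix (no raster)
toy_patch_graph <- function(areas, dmat, A_L) {
  n <- length(areas)
  nodes <- data.frame(id = seq_len(n), area_ha = areas,
                      centroid_x = seq_len(n), centroid_y = 0)
  pr <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), nrow = 2)
  edges <- data.frame(i = pr[1, ], j = pr[2, ],
                      d = if (ncol(pr)) dmat[t(pr)] else numeric(0))
  structure(list(nodes = nodes, edges = edges,
                 paths = rep(list(cbind(row = integer(0), col = integer(0))),
                             ncol(pr)),
                 landscape_area_ha = A_L, cell_size = 30, origin = c(0, 0),
                 dim = c(2L, 2L)),
            class = "patch_graph")
}

# uniform resistance surface helper
uniform_resistance <- function(nr, nc, value = 1, cell_size = 30) {
  g <- grid_raster(matrix(value, nr, nc), cell_size = cell_size)
  class(g) <- c("resistance_surface", "grid_raster")
  g
}
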