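# Grid-graph machinery shared by the least-cost-path, patch and circuit code.
# Cells are vertices (column-major index r + (c-1)*nrow); moves are 4- or
# 8-neighbour; the cost of a move is the mean of the two cell resistances
# times the centre distance (cell_size, x sqrt(2) diagonally). Cells with
# non-finite resistance are non-conductive and excluded.

# edge list among conductive cells: matrix cols a, b, mult (1 or sqrt(2))
grid_edge_pairs <- function(ok, neighbors = 8) {
  nr <- nrow(ok); nc <- ncol(ok)
  id <- matrix(seq_len(nr * nc), nr, nc)
  pair <- function(ia, ib, mult) {
    ia <- as.vector(ia); ib <- as.vector(ib)   # never 2-col matrix indexing
    keep <- ok[ia] & ok[ib]
    cbind(a = ia[keep], b = ib[keep], mult = rep(mult, sum(keep)))
  }
  e <- list(
    pair(id[, -nc, drop = FALSE], id[, -1, drop = FALSE], 1),    # horizontal
    pair(id[-nr, , drop = FALSE], id[-1, , drop = FALSE], 1))    # vertical
  if (neighbors == 8 && nr > 1 && nc > 1) {
    e <- c(e, list(
      pair(id[-nr, -nc, drop = FALSE], id[-1, -1, drop = FALSE], sqrt(2)),
      pair(id[-1, -nc, drop = FALSE], id[-nr, -1, drop = FALSE], sqrt(2))))
  }
  do.call(rbind, e)
}

# weighted edges over a resistance matrix; weight = mean(res) * cs * mult
cost_edges <- function(res_values, cell_size, neighbors = 8) {
  ok <- is.finite(res_values)
  e <- grid_edge_pairs(ok, neighbors)
  w <- (res_values[e[, "a"]] + res_values[e[, "b"]]) / 2 * cell_size *
    e[, "mult"]
  list(edges = e[, c("a", "b"), drop = FALSE], weights = w,
       n = length(res_values))
}

# igraph over the grid plus `n_virtual` extra vertices (for patch super-nodes)
cost_graph <- function(resistance, neighbors = 8, extra_edges = NULL,
                       extra_weights = NULL, n_virtual = 0) {
  ce <- cost_edges(resistance$values, resistance$cell_size, neighbors)
  el <- ce$edges; w <- ce$weights
  if (!is.null(extra_edges)) {
    el <- rbind(el, extra_edges)
    w <- c(w, extra_weights)
  }
  g <- igraph::make_empty_graph(n = ce$n + n_virtual, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- w
  g
}

cells_to_index <- function(grid, cells) {
  if (is.matrix(cells)) cells[, 1] + (cells[, 2] - 1L) * nrow(grid$values)
  else as.integer(cells)
}

index_to_cells <- function(grid, idx) {
  nr <- nrow(grid$values)
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

#' Least-cost distance and path between two cell sets
#'
#' Minimum accumulated movement cost over 4/8-neighbour moves, where a move
#' between adjacent cells costs the mean of their resistances times the
#' centre distance. Multi-cell sources/targets are handled with zero-cost
#' virtual super-nodes, so the result is the minimum over all source/target
#' cell combinations.
#'
#' @param resistance A `resistance_surface` (or any `grid_raster` of costs;
#'   non-finite cells are impassable).
#' @param source_cells,target_cells Cells as a 2-column (row, col) matrix or
#'   a vector of column-major cell indices.
#' @param neighbors 4 or 8 (default 8).
#' @return List: `distance` (cost units; `Inf` if unreachable) and `path`
#'   (matrix of row, col along one optimal route; empty when unreachable).
#' @export
cost_distance <- function(resistance, source_cells, target_cells,
                          neighbors = 8) {
  src <- cells_to_index(resistance, source_cells)
  tgt <- cells_to_index(resistance, target_cells)
  if (!length(src) || !length(tgt)) stop("sources and targets must be non-empty")
  n <- length(resistance$values)
  if (any(c(src, tgt) < 1L | c(src, tgt) > n)) stop("cells outside the grid")
  vs <- n + 1L; vt <- n + 2L
  extra <- rbind(cbind(rep(vs, length(src)), src),
                 cbind(rep(vt, length(tgt)), tgt))
  g <- cost_graph(resistance, neighbors, extra_edges = extra,
                  extra_weights = rep(0, nrow(extra)), n_virtual = 2L)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = vs, to = vt, output = "both"))
  vpath <- as.integer(sp$vpath[[1]])
  if (length(vpath) == 0L) {
    return(list(distance = Inf, path = index_to_cells(resistance, integer(0))))
  }
  d <- sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
  cells <- vpath[vpath <= n]
  list(distance = d, path = index_to_cells(resistance, cells))
}

#' Cost-weighted distance (CWD) surface from a source cell set
#'
#' Accumulated least cost from the nearest source cell to every cell of the
#' grid (the Linkage-Mapper CWD building block).
#'
#' @inheritParams cost_distance
#' @param source_cells Source cells as a 2-column (row, col) matrix or a
#'   vector of column-major cell indices.
#' @return A `grid_raster` of accumulated costs (`Inf` where unreachable,
#'   `NA` on non-conductive cells).
#' @export
cost_weighted_distance <- function(resistance, source_cells, neighbors = 8) {
  src <- cells_to_index(resistance, source_cells)
  n <- length(resistance$values)
  vs <- n + 1L
  extra <- cbind(rep(vs, length(src)), src)
  g <- cost_graph(resistance, neighbors, extra_edges = extra,
                  extra_weights = rep(0, length(src)), n_virtual = 1L)
  d <- suppressWarnings(as.numeric(igraph::distances(g, v = vs)))[seq_len(n)]
  out <- resistance
  out$values <- matrix(d, nrow(resistance$values), ncol(resistance$values))
  out$values[!is.finite(resistance$values)] <- NA_real_
  class(out) <- "grid_raster"
  attributes(out)$k <- NULL; attributes(out)$threshold <- NULL
  out
}
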