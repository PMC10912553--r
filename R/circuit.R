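# Circuit-theory current mapping. The resistance grid becomes a resistor
# network: conductive cells are nodes, adjacent cells are joined by a
# resistor equal to the mean of their cell resistances times the centre
# distance (so conductance g = 1 / (mean resistance x distance), diagonals
# scaled by sqrt(2)). Kirchhoff's laws give a sparse Laplacian system solved
# with a Cholesky factorization that is reused across injection pairs.

circuit_network <- function(resistance, neighbors = 8) {
  ok <- which(is.finite(resistance$values))
  node_of <- rep(NA_integer_, length(resistance$values))
  node_of[ok] <- seq_along(ok)
  ce <- cost_edges(resistance$values, resistance$cell_size, neighbors)
  u <- node_of[ce$edges[, 1]]; v <- node_of[ce$edges[, 2]]
  g <- 1 / ce$weights
  list(cells = ok, node_of = node_of, u = u, v = v, g = g,
       n = length(ok))
}

laplacian <- function(net, u = net$u, v = net$v, g = net$g, n = net$n) {
  Matrix::sparseMatrix(
    i = c(u, v, u, v), j = c(v, u, u, v), x = c(-g, -g, g, g),
    dims = c(n, n))
}

# voltages for injection +1 A at node s, -1 A at node t (reference node ref
# held at 0; currents are independent of the reference). `ch` is a Cholesky
# factor of the Laplacian with row/col `ref` removed.
pair_voltages <- function(ch, n, ref, s, t) {
  b <- numeric(n)
  b[s] <- b[s] + 1
  b[t] <- b[t] - 1
  b <- b[-ref]
  vv <- as.numeric(Matrix::solve(ch, b))
  out <- numeric(n)
  out[-ref] <- vv
  out
}

# per-cell current density from node voltages: half the sum of absolute
# incident edge currents; terminal cells instead carry the full current
# through them (1 A at a single-cell terminal).
node_currents <- function(net, volt, terminals) {
  I <- net$g * abs(volt[net$u] - volt[net$v])
  cur <- numeric(net$n)
  acc <- rowsum(c(I, I), c(net$u, net$v), reorder = FALSE)
  cur[as.integer(rownames(acc))] <- acc[, 1] / 2
  cur[terminals] <- 2 * cur[terminals]
  cur
}

assert_connected <- function(net, s, t) {
  g <- igraph::make_empty_graph(net$n, directed = FALSE)
  g <- igraph::add_edges(g, t(cbind(net$u, net$v)))
  comp <- igraph::components(g)$membership
  if (any(comp[s] != comp[t[1]]) || length(unique(comp[c(s, t)])) > 1L)
    stop("source and ground are disconnected: no conductive path")
}

#' Solve current flow between two cell sets
#'
#' Injects 1 A into the source cells (contracted to one node if several) and
#' grounds the target cells, solves Kirchhoff's node equations over the
#' resistance network, and returns per-cell current density: half the sum of
#' absolute currents on a cell's incident edges, with terminal cells carrying
#' the full current through them.
#'
#' @param resistance A `resistance_surface` / cost `grid_raster`; non-finite
#'   cells are non-conductive.
#' @param source_cells,ground_cells Cells as (row, col) matrices or
#'   column-major indices; must be disjoint and conductive.
#' @param neighbors 4 or 8.
#' @return List of class `current_map`: `current` (`grid_raster`, amps),
#'   `voltage` (`grid_raster`, source-ground potential with ground at 0 V),
#'   `effective_resistance` (ohms in cost units).
#' @export
solve_pair_current <- function(resistance, source_cells, ground_cells,
                               neighbors = 8) {
  net <- circuit_network(resistance, neighbors)
  s_cells <- cells_to_index(resistance, source_cells)
  t_cells <- cells_to_index(resistance, ground_cells)
  s <- unique(net$node_of[s_cells]); t <- unique(net$node_of[t_cells])
  if (anyNA(s) || anyNA(t)) stop("terminal cells must be conductive")
  if (length(intersect(s, t))) stop("source and ground cells overlap")
  assert_connected(net, s, t)
  # contract each terminal set to a single node
  grp <- seq_len(net$n)
  grp[s] <- s[1]; grp[t] <- t[1]
  relab <- match(grp, sort(unique(grp)))
  u2 <- relab[net$u]; v2 <- relab[net$v]
  keep <- u2 != v2
  n2 <- max(relab)
  s2 <- relab[s[1]]; t2 <- relab[t[1]]
  L <- laplacian(NULL, u2[keep], v2[keep], net$g[keep], n2)
  ref <- t2
  ch <- Matrix::Cholesky(L[-ref, -ref, drop = FALSE], LDL = FALSE, perm = TRUE)
  volt2 <- pair_voltages(ch, n2, ref, s2, t2)
  volt <- volt2[relab]                       # per original node
  cur <- node_currents(net, volt, terminals = c(s, t))
  shape <- function(x) {
    m <- matrix(NA_real_, nrow(resistance$values), ncol(resistance$values))
    m[net$cells] <- x
    g <- resistance; g$values <- m; class(g) <- "grid_raster"
    attributes(g)$k <- NULL; attributes(g)$threshold <- NULL
    g
  }
  structure(list(current = shape(cur), voltage = shape(volt),
                 effective_resistance = volt2[s2] - volt2[t2]),
            class = "current_map")
}

#' Peripheral-node ring description
#'
#' @param buffer_width Buffer width in cells (default 20 % of the larger grid
#'   dimension).
#' @param buffer_resistance Resistance filling the buffer (default: mean
#'   finite interior resistance, set when the map is run).
#' @param n_nodes Number of injection nodes evenly spaced on the outer ring
#'   (>= 2; default 16).
#' @return List of class `peripheral_ring`.
#' @export
peripheral_ring <- function(buffer_width = NULL, buffer_resistance = NULL,
                            n_nodes = 16) {
  if (n_nodes < 2) stop("need at least 2 peripheral nodes")
  structure(list(buffer_width = buffer_width,
                 buffer_resistance = buffer_resistance,
                 n_nodes = as.integer(n_nodes)),
            class = "peripheral_ring")
}

# perimeter cell indices of an nr x nc grid, clockwise from the top-left
perimeter_cells <- function(nr, nc) {
  top <- cbind(1L, seq_len(nc))
  right <- cbind(seq(2L, nr), nc)
  bottom <- cbind(nr, seq(nc - 1L, 1L))
  left <- cbind(seq(nr - 1L, 2L), 1L)
  rc <- rbind(top, right, bottom, left)
  rc[, 1] + (rc[, 2] - 1L) * nr
}

#' Peripheral-node current-density map
#'
#' Current injected directly at habitat nodes spikes around the node and
#' biases interpretation, so the resistance surface is padded with a buffer
#' ring, injection nodes are spaced evenly along the outer ring, current is
#' solved for node pairs, and the buffer is clipped before returning the
#' mean per-cell current.
#'
#' @param resistance A `resistance_surface`.
#' @param ring A [peripheral_ring()].
#' @param pair_scheme `"all"` (all node pairs) or `"sampled"`.
#' @param n_pairs Number of sampled pairs when `pair_scheme = "sampled"`.
#' @param seed Seed for pair sampling.
#' @param neighbors 4 or 8.
#' @return List of class `current_map`: `current` (`grid_raster`, mean amps
#'   per pair, interior only), `n_pairs`, `node_cells` (padded-grid indices),
#'   `buffer_width`, `buffer_resistance`.
#' @export
peripheral_current_map <- function(resistance, ring = peripheral_ring(),
                                   pair_scheme = c("all", "sampled"),
                                   n_pairs = 64, seed = 1L, neighbors = 8) {
  pair_scheme <- match.arg(pair_scheme)
  v <- resistance$values
  w <- ring$buffer_width
  if (is.null(w)) w <- ceiling(0.2 * max(dim(v)))
  br <- ring$buffer_resistance
  if (is.null(br)) br <- mean(v[is.finite(v)])
  nr <- nrow(v) + 2L * w; nc <- ncol(v) + 2L * w
  pad <- matrix(br, nr, nc)
  pad[w + seq_len(nrow(v)), w + seq_len(ncol(v))] <- v
  padded <- grid_raster(pad, resistance$cell_size,
                        resistance$origin + c(-w, w) * resistance$cell_size)
  per <- perimeter_cells(nr, nc)
  pos <- floor(seq(1, length(per) + 1, length.out = ring$n_nodes + 1L))
  nodes <- per[pos[seq_len(ring$n_nodes)]]
  pairs <- t(utils::combn(ring$n_nodes, 2))
  if (pair_scheme == "sampled" && nrow(pairs) > n_pairs) {
    pairs <- withr::with_seed(seed,
      pairs[sample(nrow(pairs), n_pairs), , drop = FALSE])
  }
  net <- circuit_network(padded, neighbors)
  node_ids <- net$node_of[nodes]
  if (anyNA(node_ids)) stop("ring nodes fell on non-conductive cells")
  L <- laplacian(net)
  ref <- node_ids[1]
  ch <- Matrix::Cholesky(L[-ref, -ref, drop = FALSE], LDL = FALSE,
                         perm = TRUE)
  total <- numeric(net$n)
  for (k in seq_len(nrow(pairs))) {
    s <- node_ids[pairs[k, 1]]; t <- node_ids[pairs[k, 2]]
    volt <- pair_voltages(ch, net$n, ref, s, t)
    total <- total + node_currents(net, volt, terminals = c(s, t))
  }
  mean_cur <- total / nrow(pairs)
  m <- matrix(NA_real_, nr, nc)
  m[net$cells] <- mean_cur
  interior <- m[w + seq_len(nrow(v)), w + seq_len(ncol(v)), drop = FALSE]
  out <- resistance
  out$values <- interior
  class(out) <- "grid_raster"
  attributes(out)$k <- NULL; attributes(out)$threshold <- NULL
  structure(list(current = out, n_pairs = nrow(pairs), node_cells = nodes,
                 buffer_width = w, buffer_resistance = br),
            class = "current_map")
}
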