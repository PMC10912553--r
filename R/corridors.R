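#' Normalized least-cost corridor between two patches
#'
#' For every cell x, `NC(x) = CWD_i(x) + CWD_j(x) - d_ij`: the extra cost of
#' the best i-to-j route forced through x, zero exactly on an optimal path.
#' The corridor mask keeps cells with `NC <= cutoff`.
#'
#' @param resistance A `resistance_surface`.
#' @param patch_i,patch_j Cell sets as (row, col) matrices (e.g.
#'   `patches$patches[[k]]$cells`).
#' @param cutoff Corridor width cutoff in cost units (default 200000).
#' @param neighbors 4 or 8.
#' @return List of class `corridor`: `nc` (`grid_raster`), `mask` (binary
#'   `grid_raster`), `d_ij`, `cutoff`, `empty` (TRUE when the pair is
#'   unreachable).
#' @export
normalized_corridor <- function(resistance, patch_i, patch_j,
                                cutoff = 2e5, neighbors = 8) {
  cwd_i <- cost_weighted_distance(resistance, patch_i, neighbors)
  cwd_j <- cost_weighted_distance(resistance, patch_j, neighbors)
  d_ij <- min(cwd_i$values[cells_to_index(resistance, patch_j)])
  nc <- cwd_i
  nc$values <- cwd_i$values + cwd_j$values - d_ij
  nc$values[nc$values < 0] <- 0   # numerical residue on the optimal path
  mask <- nc
  mask$values <- (is.finite(nc$values) & nc$values <= cutoff) + 0
  structure(list(nc = nc, mask = mask, d_ij = d_ij, cutoff = cutoff,
                 empty = !is.finite(d_ij)),
            class = "corridor")
}

#' Pinch points: circuit current confined to a corridor
#'
#' Resistance outside the corridor mask is made non-conductive and 1 A is
#' run from patch i to patch j. Cells where the remaining current
#' concentrates (narrow necks carrying most of the 1 A) are pinch points —
#' linkages with few alternative routes.
#'
#' @param resistance A `resistance_surface`.
#' @param corridor A [normalized_corridor()] result.
#' @param patch_i,patch_j Cell sets as (row, col) matrices.
#' @param neighbors 4 or 8.
#' @return A `current_map` whose `current` raster is zero outside the
#'   corridor mask.
#' @export
pinch_points <- function(resistance, corridor, patch_i, patch_j,
                         neighbors = 8) {
  if (corridor$empty || !any(corridor$mask$values == 1, na.rm = TRUE))
    stop("empty corridor mask")
  res2 <- resistance
  res2$values[corridor$mask$values != 1] <- Inf
  keep_i <- corridor$mask$values[patch_i] == 1
  keep_j <- corridor$mask$values[patch_j] == 1
  cm <- tryCatch(
    solve_pair_current(res2, patch_i[keep_i, , drop = FALSE],
                       patch_j[keep_j, , drop = FALSE], neighbors),
    error = function(e)
      stop("corridor mask disconnects the pair: ", conditionMessage(e)))
  cm$current$values[corridor$mask$values != 1] <- 0
  cm$current$values[is.na(cm$current$values)] <- 0
  cm
}

#' Moving-window barrier scan
#'
#' Slides a circular restoration window over the grid: inside the window the
#' resistance is set to `restored_value` (fully restored habitat), all
#' patch-pair least-cost distances are recomputed, and the window scores the
#' largest pairwise improvement divided by the window diameter (cost units
#' saved per metre of restoration). High scores mark removable barriers whose
#' mitigation would most improve connectivity.
#'
#' @param resistance A `resistance_surface`.
#' @param patches A `patch_set` (>= 2 patches) whose pairwise LCPs define
#'   the baseline.
#' @param radius Window radius in metres (>= cell size).
#' @param stride Window-centre lattice spacing in cells (default 1).
#' @param restored_value Resistance inside the restored window (default 1).
#' @param pairs Optional 2-column matrix of patch index pairs to evaluate
#'   (default: all pairs).
#' @param neighbors 4 or 8.
#' @return List of class `barrier_map`: `scores` (`grid_raster`, zero away
#'   from window centres), `radius`, `stride`, `baseline` (pair distances).
#' @export
barrier_scan <- function(resistance, patches, radius, stride = 1L,
                         restored_value = 1, pairs = NULL, neighbors = 8) {
  if (radius < resistance$cell_size)
    stop("radius must be at least one cell")
  np <- length(patches$patches)
  if (np < 2) stop("need at least two patches")
  if (is.null(pairs)) pairs <- t(utils::combn(np, 2))
  base <- apply(pairs, 1, function(pr)
    cost_distance(resistance, patches$patches[[pr[1]]]$cells,
                  patches$patches[[pr[2]]]$cells, neighbors)$distance)
  nr <- nrow(resistance$values); nc <- ncol(resistance$values)
  centers_r <- seq(1L, nr, by = stride)
  centers_c <- seq(1L, nc, by = stride)
  rcell <- radius / resistance$cell_size
  scores <- matrix(0, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (cr in centers_r) for (cc in centers_c) {
    disc <- (rows - cr)^2 + (cols - cc)^2 <= rcell^2
    res2 <- resistance
    res2$values[disc] <- restored_value
    restored <- apply(pairs, 1, function(pr)
      cost_distance(res2, patches$patches[[pr[1]]]$cells,
                    patches$patches[[pr[2]]]$cells, neighbors)$distance)
    imp <- max(pmax(base - restored, 0))
    scores[cr, cc] <- imp / (2 * radius)
  }
  grid <- resistance
  grid$values <- scores
  class(grid) <- "grid_raster"
  attributes(grid)$k <- NULL; attributes(grid)$threshold <- NULL
  structure(list(scores = grid, radius = radius, stride = stride,
                 baseline = data.frame(i = pairs[, 1], j = pairs[, 2],
                                       d = base)),
            class = "barrier_map")
}
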