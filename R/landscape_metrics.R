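#' Clumpiness (CLUMPY) of a habitat class
#'
#' Measures habitat aggregation against the random expectation, insensitive
#' to habitat abundance. With G the proportion of the habitat cells'
#' 4-neighbour adjacencies (double-counted, raster-interior pairs only, no
#' landscape-border padding) that join habitat to habitat, and P the habitat
#' proportion of valid cells:
#' `CLUMPY = (G - P) / (1 - P)` when `G >= P`, otherwise `(G - P) / P` when
#' `P < 0.5` and `(G - P) / (1 - P)` when `P >= 0.5`. Ranges from -1
#' (maximally disaggregated, e.g. a checkerboard) through 0 (random) to 1
#' (one solid clump).
#'
#' @param habitat Binary `grid_raster` (NA cells excluded everywhere).
#' @return CLUMPY in \[-1, 1\]; `NA` when the landscape is entirely habitat
#'   or entirely background.
#' @export
clumpiness <- function(habitat) {
  v <- habitat$values
  valid <- is.finite(v)
  if (!any(valid & v == 1)) stop("no habitat cells")
  P <- mean(v[valid] == 1)
  if (P == 1) return(NA_real_)
  hab <- valid & v == 1
  e <- grid_edge_pairs(valid, neighbors = 4)
  from_h <- hab[e[, "a"]]; to_h <- hab[e[, "b"]]
  g_hh <- 2 * sum(from_h & to_h)
  g_h <- sum(from_h) + sum(to_h)        # ordered adjacencies out of habitat
  if (g_h == 0) return(NA_real_)
  G <- g_hh / g_h
  if (G >= P || P >= 0.5) (G - P) / (1 - P) else (G - P) / P
}

#' Connectance (CONNECT) of a patch set
#'
#' The percentage of patch pairs closer than a species-specific dispersal
#' threshold: `100 x (pairs with edge-to-edge distance <= threshold) /
#' (n (n - 1) / 2)`. Edge-to-edge distance is the minimum Euclidean distance
#' between boundary-cell centres of the two patches (grid-native and
#' unambiguous at 30 m).
#'
#' @param patches A `patch_set`.
#' @param threshold Distance threshold in metres.
#' @return Percent in \[0, 100\]; `NA` when fewer than 2 patches.
#' @export
connectance <- function(patches, threshold) {
  np <- length(patches$patches)
  if (np < 2) return(NA_real_)
  bnd <- lapply(patches$patches, function(p)
    cell_xy(patches$labels, p$cells[, 1], p$cells[, 2])[
      boundary_rows(patches$labels, p$cells), , drop = FALSE])
  pairs <- utils::combn(np, 2)
  within <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- bnd[[pairs[1, k]]]; b <- bnd[[pairs[2, k]]]
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    min(d2) <= threshold^2
  }, TRUE)
  100 * mean(within)
}

# rows of `cells` on the patch boundary (some 4-neighbour missing from patch)
boundary_rows <- function(labels, cells) {
  v <- labels$values
  nr <- nrow(v); nc <- ncol(v)
  id <- v[cells]
  inside <- rep(TRUE, nrow(cells))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r <- cells[, 1] + d[1]; c2 <- cells[, 2] + d[2]
    ok <- r >= 1L & r <= nr & c2 >= 1L & c2 <= nc
    nb <- rep(FALSE, nrow(cells))
    nb[ok] <- v[cbind(r[ok], c2[ok])] == id[ok]
    inside <- inside & nb
  }
  which(!inside)
}
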