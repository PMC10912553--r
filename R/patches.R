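#' Label habitat patches (connected components)
#'
#' Habitat cells are grouped into patches under 8-neighbour adjacency by
#' default (diagonal contact counts, the common habitat-patch convention);
#' 4-neighbour is switchable. Patch area is
#' `cells x cell_size^2 / 10000` ha (0.09 ha per 30 m cell).
#'
#' @param habitat Binary `grid_raster` (1 = habitat; `NA` ignored).
#' @param connectivity 4 or 8 (default 8).
#' @return List of class `patch_set`: `patches` (list with `id`, `cells`
#'   (row/col matrix), `area_ha`, `centroid`), `labels` (`grid_raster` of
#'   patch ids, 0 = background), `geometry` fields, `min_area_ha` applied.
#' @export
label_patches <- function(habitat, connectivity = 8) {
  v <- habitat$values
  if (!all(v[is.finite(v)] %in% c(0, 1))) stop("habitat raster must be binary")
  hab <- is.finite(v) & v == 1
  lab <- matrix(0L, nrow(v), ncol(v))
  ids <- integer(0)
  if (any(hab)) {
    e <- grid_edge_pairs(hab, connectivity)
    g <- igraph::make_empty_graph(length(v), directed = FALSE)
    g <- igraph::add_edges(g, t(e[, c("a", "b"), drop = FALSE]))
    comp <- igraph::components(g)$membership
    hcells <- which(hab)
    lab[hcells] <- as.integer(factor(comp[hcells]))
    ids <- sort(unique(lab[hcells]))
  }
  cs <- habitat$cell_size
  patches <- lapply(ids, function(i) {
    idx <- which(lab == i)
    rc <- index_to_cells(habitat, idx)
    ctr <- cell_xy(habitat, rc[, 1], rc[, 2])
    list(id = i, cells = rc, area_ha = nrow(rc) * cs^2 / 1e4,
         centroid = c(x = mean(ctr[, 1]), y = mean(ctr[, 2])))
  })
  labels <- habitat
  labels$values <- lab + 0
  structure(list(patches = patches, labels = labels,
                 cell_size = cs, origin = habitat$origin,
                 min_area_ha = 0),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  a <- patch_areas(x)
  cat(sprintf("<patch_set> %d patches, %.2f ha total (min area applied %.2f ha)\n",
              length(x$patches), sum(a), x$min_area_ha))
  invisible(x)
}

#' Patch areas (ha)
#' @param patches A `patch_set`.
#' @return Numeric vector of areas in patch order.
#' @export
patch_areas <- function(patches)
  vapply(patches$patches, `[[`, 0, "area_ha")

#' Patch summary table
#' @param patches A `patch_set`.
#' @return Data frame: `id`, `area_ha`, `centroid_x`, `centroid_y`.
#' @export
patch_table <- function(patches) {
  data.frame(
    id = vapply(patches$patches, `[[`, 0L, "id"),
    area_ha = patch_areas(patches),
    centroid_x = vapply(patches$patches, function(p) p$centroid[["x"]], 0),
    centroid_y = vapply(patches$patches, function(p) p$centroid[["y"]], 0))
}

#' Minimum viable patch area from occupied patches (20 % rule)
#'
#' For species without a published minimum viable habitat area: collect one
#' patch-area record per occurrence that falls inside a patch (patches with
#' several occurrences contribute several records), sort ascending, drop the
#' smallest `floor(drop_fraction * n)` records, and return the smallest
#' retained area. The records dropped are the ones most likely to represent
#' marginal habitat fragments, by analogy with the 10th-percentile threshold
#' on suitability scores.
#'
#' @param patches A `patch_set`.
#' @param occ An `occurrence_set`.
#' @param drop_fraction Fraction of smallest records dropped (default 0.2).
#' @return Minimum viable patch area in ha.
#' @export
min_patch_from_occupied <- function(patches, occ, drop_fraction = 0.2) {
  rc <- xy_cell(patches$labels, occ$x, occ$y)
  ok <- !is.na(rc[, 1])
  lab <- rep(0L, nrow(occ))
  lab[ok] <- patches$labels$values[rc[ok, , drop = FALSE]]
  lab <- lab[lab > 0]
  if (!length(lab)) stop("no occurrence falls inside a patch")
  areas <- patch_areas(patches)
  ids <- vapply(patches$patches, `[[`, 0L, "id")
  rec <- sort(areas[match(lab, ids)])
  drop <- floor(drop_fraction * length(rec))
  rec[drop + 1L]
}

#' Filter a patch set by minimum area
#'
#' Patches below `min_area` are removed from the patch list and zeroed in the
#' label raster; surviving patches keep their ids.
#'
#' @param patches A `patch_set`.
#' @param min_area Minimum viable patch area in ha (>= 0).
#' @return Filtered `patch_set`.
#' @export
filter_patches <- function(patches, min_area) {
  if (min_area < 0) stop("min_area must be >= 0")
  keep <- patch_areas(patches) >= min_area
  dropped <- patches$patches[!keep]
  for (p in dropped) patches$labels$values[p$cells] <- 0
  patches$patches <- patches$patches[keep]
  patches$min_area_ha <- max(patches$min_area_ha, min_area)
  patches
}
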