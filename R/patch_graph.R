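#' Negative-exponential dispersal kernel
#'
#' `p(d) = exp(-alpha * d)` with `alpha` calibrated so the probability at the
#' species' median dispersal distance is 0.5 (the standard Graphab
#' calibration). Distances are in accumulated-cost units, with the convention
#' that cost equals metres where resistance is 1 — so dispersal distances
#' reported in km apply directly.
#'
#' @param d_med Median dispersal distance (cost units = metres at
#'   resistance 1).
#' @return List of class `dispersal_kernel`: `alpha`, `d_med`.
#' @export
dispersal_kernel <- function(d_med) {
  if (d_med <= 0) stop("d_med must be > 0")
  structure(list(alpha = log(2) / d_med, d_med = d_med),
            class = "dispersal_kernel")
}

#' Build the least-cost-path patch graph
#'
#' A complete graph over the habitat patches: every pair is linked by its
#' least-cost path over the resistance surface — all links are formed
#' regardless of distance, for a complete view of the patch network.
#' Patch-to-patch cost is the minimum over all pairs of member cells (LCP
#' software semantics; patch interiors are crossable at their own
#' resistance).
#'
#' @param patches A `patch_set` (>= 1 patch).
#' @param resistance A `resistance_surface` aligned with the patches.
#' @param neighbors 4 or 8.
#' @param landscape_area_ha Total landscape area `A_L` for the PC
#'   denominator; defaults to the full raster area.
#' @return List of class `patch_graph`: `nodes` (patch table with areas),
#'   `edges` (data frame `i`, `j`, `d`), `paths` (list of row/col LCP
#'   matrices, parallel to `edges`), `landscape_area_ha`, `geometry`.
#' @export
build_graph <- function(patches, resistance, neighbors = 8,
                        landscape_area_ha = NULL) {
  np <- length(patches$patches)
  if (np < 1) stop("need at least one patch")
  stopifnot_aligned(patches$labels, resistance, "patches and resistance")
  if (is.null(landscape_area_ha))
    landscape_area_ha <- length(resistance$values) *
      resistance$cell_size^2 / 1e4
  nodes <- patch_table(patches)
  pairs <- if (np >= 2) utils::combn(np, 2) else
    matrix(integer(0), nrow = 2)
  edges <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  paths <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cd <- cost_distance(resistance, patches$patches[[a]]$cells,
                        patches$patches[[b]]$cells, neighbors)
    edges <- rbind(edges, data.frame(i = nodes$id[a], j = nodes$id[b],
                                     d = cd$distance))
    paths[[k]] <- cd$path
  }
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 landscape_area_ha = landscape_area_ha,
                 cell_size = resistance$cell_size,
                 origin = resistance$origin,
                 dim = dim(resistance$values)),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d patches, %d links, A_L = %.1f ha\n",
              nrow(x$nodes), nrow(x$edges), x$landscape_area_ha))
  invisible(x)
}

# symmetric matrices of direct (p) and best multi-step (pstar) dispersal
# probabilities between patches; pstar via shortest paths on -log p weights
dispersal_probabilities <- function(graph, kernel, subset = NULL) {
  ids <- graph$nodes$id
  if (is.null(subset)) subset <- ids
  n <- length(subset)
  p <- diag(1, n)
  if (n >= 2 && nrow(graph$edges)) {
    e <- graph$edges[graph$edges$i %in% subset & graph$edges$j %in% subset, ]
    ii <- match(e$i, subset); jj <- match(e$j, subset)
    pd <- exp(-kernel$alpha * e$d)
    p[cbind(ii, jj)] <- pd
    p[cbind(jj, ii)] <- pd
    w <- kernel$alpha * e$d           # -log p, additive over links
    g <- igraph::make_empty_graph(n, directed = FALSE)
    keep <- is.finite(w)
    g <- igraph::add_edges(g, t(cbind(ii, jj)[keep, , drop = FALSE]))
    igraph::E(g)$weight <- w[keep]
    D <- igraph::distances(g)
    pstar <- exp(-D)
  } else {
    pstar <- p
  }
  diag(pstar) <- 1
  list(p = p, pstar = pstar, ids = subset)
}

#' Probability of Connectivity (PC)
#'
#' `PC = sum_i sum_j a_i a_j p*_ij / A_L^2`, where `p*_ij` is the maximum
#' product of per-link dispersal probabilities over all patch-graph routes
#' from i to j (computed as a shortest path on `-log p` weights) and
#' `p*_ii = 1`. Bounded by 1 (all habitat, perfectly connected).
#'
#' @param graph A `patch_graph`.
#' @param kernel A `dispersal_kernel`.
#' @return PC in \[0, 1\].
#' @export
pc_index <- function(graph, kernel) {
  if (graph$landscape_area_ha <= 0) stop("landscape area must be > 0")
  a <- graph$nodes$area_ha
  dp <- dispersal_probabilities(graph, kernel)
  sum(outer(a, a) * dp$pstar) / graph$landscape_area_ha^2
}

#' Per-patch dPC and its intra/flux/connector decomposition
#'
#' `dPC_k = 100 (PC - PC_without_k) / PC`: the percentage of the Probability
#' of Connectivity lost when patch k is removed. It splits exactly into
#' `dPCintra` (the patch's own area term `a_k^2`), `dPCflux`
#' (`2 sum_{j != k} a_k a_j p*_kj`, dispersal flux into/out of k) and
#' `dPCconnector` (the remainder: the patch's stepping-stone contribution to
#' other pairs' best routes; 0 for patches on no optimal route).
#'
#' @param graph A `patch_graph`.
#' @param kernel A `dispersal_kernel`.
#' @return Data frame: `id`, `area_ha`, `dPC`, `dPCintra`, `dPCflux`,
#'   `dPCconnector` (all percentages).
#' @export
dpc <- function(graph, kernel) {
  a <- graph$nodes$area_ha
  ids <- graph$nodes$id
  AL2 <- graph$landscape_area_ha^2
  dp <- dispersal_probabilities(graph, kernel)
  PC <- sum(outer(a, a) * dp$pstar) / AL2
  if (PC <= 0) stop("PC = 0: dPC undefined")
  out <- data.frame(id = ids, area_ha = a, dPC = NA_real_,
                    dPCintra = NA_real_, dPCflux = NA_real_,
                    dPCconnector = NA_real_)
  for (k in seq_along(ids)) {
    rest <- ids[-k]
    PC_wo <- if (length(rest)) {
      dpk <- dispersal_probabilities(graph, kernel, subset = rest)
      sum(outer(a[-k], a[-k]) * dpk$pstar) / AL2
    } else 0
    dPC <- 100 * (PC - PC_wo) / PC
    intra <- 100 * a[k]^2 / (AL2 * PC)
    flux <- 100 * 2 * sum(a[k] * a[-k] * dp$pstar[k, -k]) / (AL2 * PC)
    out$dPC[k] <- dPC
    out$dPCintra[k] <- intra
    out$dPCflux[k] <- if (length(rest)) flux else 0
    out$dPCconnector[k] <- dPC - intra - out$dPCflux[k]
  }
  out
}
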