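#' Rasterize a patch graph's least-cost paths
#'
#' A binary raster with 1 wherever any LCP cell path of the graph passes —
#' per-species, so a cell crossed by many of one species' paths still counts
#' once toward multi-species overlap.
#'
#' @param graph A `patch_graph`.
#' @return Binary `grid_raster` on the graph's source geometry.
#' @export
rasterize_lcps <- function(graph) {
  v <- matrix(0, graph$dim[1], graph$dim[2])
  for (p in graph$paths) {
    if (nrow(p)) v[p] <- 1
  }
  grid_raster(v, graph$cell_size, graph$origin)
}

#' Multi-species linkage summation
#'
#' Cell-wise sum of per-species binary LCP rasters: the count of species
#' whose least-cost linkages cross each cell (the shared-corridor map).
#'
#' @param lcp_rasters List of aligned binary `grid_raster`s, one per species.
#' @return `grid_raster` of integer counts in \[0, n_species\].
#' @export
sum_species <- function(lcp_rasters) {
  if (!length(lcp_rasters)) stop("no rasters supplied")
  out <- lcp_rasters[[1]]
  for (r in lcp_rasters[-1]) {
    stopifnot_aligned(out, r, "LCP rasters")
    out$values <- out$values + r$values
  }
  out
}

#' Run the full per-site multi-species analysis
#'
#' Orchestrates, per species: occurrence thinning, suitability thresholding
#' (MSSS against a random background sample, or the 10th-percentile presence
#' rule), binarization, the negative-exponential resistance surface with
#' road mosaicking, patch extraction with the minimum-viable-patch rule,
#' the least-cost patch graph with PC/dPC, the clumpiness and connectance
#' metrics, and the rasterized LCPs; then sums the per-species LCP rasters
#' into the multi-species linkage map and (when the occurrence cluster
#' qualifies) computes the site composition report. Heavier raster stages
#' (peripheral current, corridors/pinch points, barriers) are off by default
#' and switchable via `stages`.
#'
#' @param scene A [synthetic_scene()] (or a list with the same elements).
#' @param profiles List of [species_profile()]s; species absent from the
#'   scene's occurrences are skipped with a warning.
#' @param config List of overrides: `thin_spacing` (m, 1000), `thin_min_n`
#'   (records kept before the spacing is relaxed, 20), `n_background` (1000), `k` (8), `road_buffer` (m, 30),
#'   `connectivity` (8), `corridor_cutoff` (cost, 2e5), `barrier_radius`
#'   (m, 150), `barrier_stride` (cells, 2), `species_min` (3),
#'   `site_buffer` (m, 5000), `ring_nodes` (16), `seed` (1).
#' @param stages Character subset of `c("circuit", "corridors", "barriers")`
#'   to enable beyond the core pipeline.
#' @param outdir Optional directory: when given, all tables/rasters are
#'   written (CSV/.asc/GeoJSON) together with a `manifest.json`.
#' @return List of class `site_run`: `species` (named list of per-species
#'   results), `multi_species` (`grid_raster`), `report` (`site_report` or
#'   `NULL`), `config`, `manifest` (paths written, or `NULL`).
#' @export
run_site <- function(scene, profiles, config = list(),
                     stages = character(), outdir = NULL) {
  cfg <- utils::modifyList(list(
    thin_spacing = 1000, thin_min_n = 20, n_background = 1000, k = 8,
    road_buffer = 30,
    connectivity = 8, corridor_cutoff = 2e5, barrier_radius = 150,
    barrier_stride = 2L, species_min = 3, site_buffer = 5000,
    ring_nodes = 16, seed = 1L), config)
  if (length(stages))
    stages <- match.arg(stages, c("circuit", "corridors", "barriers"),
                        several.ok = TRUE)
  suit <- scene$suitability
  road_mask <- rasterize_roads(scene$roads, suit, cfg$road_buffer)
  cfg$bg_scores <- withr::with_seed(cfg$seed + 7L, {
    ok <- which(is.finite(suit$values))
    suit$values[sample(ok, min(cfg$n_background, length(ok)))]
  })
  results <- list()
  for (prof in profiles) {
    sp <- prof$species_id
    occ <- scene$occurrences[scene$occurrences$species_id == sp, ,
                             drop = FALSE]
    if (nrow(occ) == 0L) {
      warning("species ", sp, " has no occurrences in the scene; skipped")
      next
    }
    res <- tryCatch(
      run_species(sp, occ, prof, suit, road_mask, cfg, stages),
      error = function(e)
        stop("stage failure for species ", sp, ": ", conditionMessage(e)))
    results[[sp]] <- res
  }
  multi <- if (length(results))
    sum_species(lapply(results, `[[`, "lcp_raster")) else NULL
  report <- site_report_from_scene(scene, results, cfg)
  run <- structure(list(species = results, multi_species = multi,
                        report = report, config = cfg, manifest = NULL),
                   class = "site_run")
  if (!is.null(outdir)) run$manifest <- write_site_run(run, scene, outdir)
  run
}

run_species <- function(sp, occ, prof, suit, road_mask, cfg, stages) {
  occ_thin <- adaptive_thin_occurrences(occ, cfg$thin_spacing,
                                        cfg$thin_min_n)
  rc <- xy_cell(suit, occ_thin$x, occ_thin$y)
  pres_scores <- suit$values[rc[!is.na(rc[, 1]), , drop = FALSE]]
  thr <- if (prof$threshold_rule == "p10")
    presence_percentile_threshold(pres_scores, 10)
  else msss_threshold(pres_scores, cfg$bg_scores)
  habitat <- binarize(suit, thr)
  resist <- suitability_to_resistance(suit, thr, k = cfg$k)
  resist <- mosaic_roads(resist, road_mask, prof$road_cost)
  patches <- label_patches(habitat, cfg$connectivity)
  min_ha <- prof$min_patch_ha
  if (is.null(min_ha))
    min_ha <- min_patch_from_occupied(patches, occ_thin)
  patches <- filter_patches(patches, min_ha)
  if (!length(patches$patches))
    stop("no patch survives the ", min_ha, " ha minimum")
  kern <- dispersal_kernel(prof$dispersal_km * 1000)
  graph <- build_graph(patches, resist, cfg$connectivity)
  out <- list(
    profile = prof, threshold = thr, habitat = habitat,
    resistance = resist, patches = patches, graph = graph,
    min_patch_ha = min_ha,
    pc = pc_index(graph, kern), dpc = dpc(graph, kern),
    clumpiness = clumpiness(habitat),
    connectance = connectance(patches, prof$dispersal_km * 1000),
    boyce = tryCatch(boyce_index(suit, occ_thin)$index,
                     error = function(e) NA_real_),
    lcp_raster = rasterize_lcps(graph))
  if ("circuit" %in% stages)
    out$current <- peripheral_current_map(
      resist, peripheral_ring(n_nodes = cfg$ring_nodes),
      seed = cfg$seed, neighbors = cfg$connectivity)
  if ("corridors" %in% stages)
    out$corridors <- species_corridors(resist, patches, graph, prof, cfg)
  if ("barriers" %in% stages && length(patches$patches) >= 2)
    out$barriers <- barrier_scan(resist, patches, cfg$barrier_radius,
                                 cfg$barrier_stride,
                                 neighbors = cfg$connectivity)
  out
}

# corridors + pinch points for pairs within the species' maximum dispersal
species_corridors <- function(resist, patches, graph, prof, cfg) {
  max_d <- prof$max_dispersal_km * 1000
  sel <- which(graph$edges$d <= max_d)
  lapply(sel, function(k) {
    e <- graph$edges[k, ]
    ia <- match(e$i, graph$nodes$id); ja <- match(e$j, graph$nodes$id)
    corr <- normalized_corridor(resist, patches$patches[[ia]]$cells,
                                patches$patches[[ja]]$cells,
                                cfg$corridor_cutoff, cfg$connectivity)
    pinch <- tryCatch(
      pinch_points(resist, corr, patches$patches[[ia]]$cells,
                   patches$patches[[ja]]$cells, cfg$connectivity),
      error = function(e2) NULL)
    list(i = e$i, j = e$j, d = e$d, corridor = corr, pinch = pinch)
  })
}

site_report_from_scene <- function(scene, results, cfg) {
  if (!length(results)) return(NULL)
  cl <- cluster_occurrences(scene$occurrences, cfg$site_buffer)
  # largest cluster defines the site
  main <- which(cl == which.max(tabulate(cl)))
  area <- delineate_area(scene$occurrences[main, , drop = FALSE],
                         cfg$species_min, cfg$site_buffer)
  if (is.null(area)) return(NULL)
  composition_report(area, lapply(results, `[[`, "habitat"),
                     scene$urban_mask, scene$protected_mask)
}

#' Per-species metric summary of a site run
#'
#' @param run A `site_run`.
#' @return Data frame, one row per analysed species.
#' @export
site_summary <- function(run) {
  do.call(rbind, lapply(names(run$species), function(sp) {
    r <- run$species[[sp]]
    data.frame(species_id = sp, threshold = r$threshold$threshold,
               threshold_rule = r$threshold$rule,
               n_patches = length(r$patches$patches),
               min_patch_ha = r$min_patch_ha,
               total_habitat_ha = sum(patch_areas(r$patches)),
               pc = r$pc, boyce = r$boyce,
               clumpiness = r$clumpiness, connectance = r$connectance)
  }))
}

write_site_run <- function(run, scene, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  put("summary.csv", function(p)
    utils::write.csv(site_summary(run), p, row.names = FALSE))
  if (!is.null(run$multi_species))
    put("multi_species_lcp.asc", function(p)
      write_asc(run$multi_species, p))
  for (sp in names(run$species)) {
    r <- run$species[[sp]]
    put(paste0(sp, "_dpc.csv"), function(p)
      utils::write.csv(r$dpc, p, row.names = FALSE))
    put(paste0(sp, "_patches.csv"), function(p)
      utils::write.csv(patch_table(r$patches), p, row.names = FALSE))
    put(paste0(sp, "_edges.csv"), function(p)
      utils::write.csv(r$graph$edges, p, row.names = FALSE))
    put(paste0(sp, "_habitat.asc"), function(p) write_asc(r$habitat, p))
    put(paste0(sp, "_resistance.asc"), function(p) write_asc(r$resistance, p))
    if (!is.null(r$current))
      put(paste0(sp, "_current.asc"), function(p)
        write_asc(r$current$current, p))
    if (!is.null(r$barriers))
      put(paste0(sp, "_barriers.asc"), function(p)
        write_asc(r$barriers$scores, p))
  }
  if (!is.null(run$report)) {
    put("site_composition.csv", function(p)
      utils::write.csv(run$report$site, p, row.names = FALSE))
    put("species_composition.csv", function(p)
      utils::write.csv(run$report$species, p, row.names = FALSE))
  }
  manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(files = as.list(paths), config = run$config,
         species = names(run$species), seed = scene$seed),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(paths, manifest = manifest)
}
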