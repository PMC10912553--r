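#' @title Synthetic landscape generation
#' @description
#' Seeded generators for every input the connectivity pipeline needs:
#' spatially autocorrelated habitat-suitability surfaces (with optional
#' planted patches, corridors and barriers whose downstream recovery is the
#' package's validation surface), occurrences concentrated in suitable cells,
#' straight road polylines crossing the extent, compact urban cores and
#' scattered protected polygons. Everything is a pure function of its
#' parameters and seed.
#' @name synthetic
NULL

# separable Gaussian blur with replicate padding; sigma in cells
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

# distance from points (x, y) to segment a-b
point_segment_distance <- function(x, y, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((x - a[1])^2 + (y - a[2])^2))
  t <- pmin(1, pmax(0, ((x - a[1]) * vx + (y - a[2]) * vy) / len2))
  sqrt((x - a[1] - t * vx)^2 + (y - a[2] - t * vy)^2)
}

# minimum distance from every cell centre of `grid` to a polyline (matrix of
# vertices); returns a matrix aligned with grid$values
polyline_cell_distance <- function(grid, line) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xy <- cell_xy(grid, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  d <- rep(Inf, nr * nc)
  for (s in seq_len(nrow(line) - 1L)) {
    d <- pmin(d, point_segment_distance(xy[, 1], xy[, 2],
                                        line[s, ], line[s + 1L, ]))
  }
  matrix(d, nr, nc)
}

#' Generate an autocorrelated habitat-suitability surface
#'
#' White noise smoothed with a Gaussian kernel (sd = `correlation_length`)
#' and rescaled to \[0, 1\]: the simplest stationary autocorrelated random
#' field. Planted features are applied afterwards so their recovery by the
#' downstream corridor/circuit/barrier analyses can be asserted:
#' * `patch`: disc of raised suitability (`center`, `radius`, `value`),
#' * `corridor`: band of raised suitability along a polyline
#'   (`from`, `to` or `line`, `width`, `value`); raises via `pmax`,
#' * `barrier`: band forced to a near-zero `value` (overrides everything).
#' Geometry is in metres.
#'
#' @param shape Integer (rows, cols); at least 20 x 20.
#' @param correlation_length Autocorrelation scale in metres (> 0).
#' @param planted_features List of feature descriptors (see above).
#' @param seed Integer seed; identical seed + parameters give bit-identical
#'   output.
#' @param cell_size,origin Grid geometry (metres).
#' @param base_range Range the smoothed noise is rescaled to before features
#'   are planted; lower the top end to make the matrix uniformly poor.
#' @return A `grid_raster` with values in \[0, 1\].
#' @export
generate_suitability <- function(shape, correlation_length = 300,
                                 planted_features = list(), seed = 1L,
                                 cell_size = 30, origin = c(0, 0),
                                 base_range = c(0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (any(shape < 2L)) stop("degenerate shape: need at least 2 cells a side")
  if (any(shape < 20L)) stop("shape must be at least 20 x 20")
  if (correlation_length <= 0) stop("correlation_length must be > 0")
  v <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    gaussian_smooth(noise, correlation_length / cell_size)
  })
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  v <- base_range[1] + v * (base_range[2] - base_range[1])
  g <- grid_raster(v, cell_size = cell_size, origin = origin)
  for (f in planted_features) g <- plant_feature(g, f)
  g$values[] <- pmin(1, pmax(0, g$values))
  g
}

plant_feature <- function(grid, f) {
  type <- match.arg(f$type, c("patch", "corridor", "barrier"))
  if (type == "patch") {
    nr <- nrow(grid$values); nc <- ncol(grid$values)
    xy <- cell_xy(grid, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
    d <- matrix(sqrt((xy[, 1] - f$center[1])^2 + (xy[, 2] - f$center[2])^2),
                nr, nc)
    val <- if (is.null(f$value)) 0.95 else f$value
    grid$values[d <= f$radius] <- pmax(grid$values[d <= f$radius], val)
  } else {
    line <- if (!is.null(f$line)) f$line else rbind(f$from, f$to)
    d <- polyline_cell_distance(grid, line)
    inside <- d <= f$width / 2
    if (type == "corridor") {
      val <- if (is.null(f$value)) 0.9 else f$value
      grid$values[inside] <- pmax(grid$values[inside], val)
    } else {
      val <- if (is.null(f$value)) 0.01 else f$value
      grid$values[inside] <- val
    }
  }
  grid
}

#' Sample species occurrences biased toward suitable habitat
#'
#' Cells are drawn with probability proportional to
#' `suitability^sampling_exponent` (0 = uniform over valid cells) and points
#' are jittered uniformly within the chosen cell: sub-cell position carries no
#' information at the 30 m analysis grain.
#'
#' @param suitability A `grid_raster` in \[0, 1\].
#' @param n Number of points (>= 1).
#' @param species_id Character label attached to every record.
#' @param sampling_exponent Habitat-bias exponent (>= 0).
#' @param seed Integer seed.
#' @return Data frame (`occurrence_set`) with columns
#'   `species_id`, `x`, `y`.
#' @export
sample_occurrences <- function(suitability, n, species_id = "sp1",
                               sampling_exponent = 2, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  v <- suitability$values
  ok <- which(is.finite(v))
  w <- v[ok]^sampling_exponent
  if (all(w == 0)) stop("all-zero suitability: occurrence sampling has no support")
  withr::with_seed(seed, {
    cells <- sample(ok, n, replace = TRUE, prob = w)
    rc <- cbind(row = ((cells - 1L) %% nrow(v)) + 1L,
                col = ((cells - 1L) %/% nrow(v)) + 1L)
    ctr <- cell_xy(suitability, rc[, 1], rc[, 2])
    cs <- suitability$cell_size
    occurrence_set(species_id = species_id,
                   x = ctr[, 1] + stats::runif(n, -cs / 2, cs / 2),
                   y = ctr[, 2] + stats::runif(n, -cs / 2, cs / 2))
  })
}

#' Construct an occurrence set
#'
#' @param species_id,x,y Vectors (recycled to common length); coordinates in
#'   metres.
#' @return Data frame of class `occurrence_set`.
#' @export
occurrence_set <- function(species_id = character(), x = numeric(),
                           y = numeric()) {
  df <- data.frame(species_id = as.character(species_id),
                   x = as.numeric(x), y = as.numeric(y))
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Generate straight roads crossing the extent
#'
#' Each road is a 2-vertex polyline from a uniformly-drawn point on one
#' boundary edge to a point on a different edge, so every road intersects the
#' extent boundary exactly twice.
#'
#' @param shape Integer (rows, cols) of the reference grid.
#' @param n_roads Number of roads (>= 0).
#' @param seed Integer seed.
#' @param cell_size,origin Grid geometry.
#' @return List of 2 x 2 vertex matrices (columns x, y); empty list when
#'   `n_roads = 0`.
#' @export
generate_roads <- function(shape, n_roads, seed = 1L, cell_size = 30,
                           origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (n_roads < 0) stop("n_roads must be >= 0")
  if (n_roads == 0) return(list())
  W <- shape[2] * cell_size; H <- shape[1] * cell_size
  x0 <- origin[1]; ytop <- origin[2]
  edge_point <- function(e, t) switch(e,
    cbind(x0 + t * W, ytop),          # top
    cbind(x0 + W, ytop - t * H),      # right
    cbind(x0 + t * W, ytop - H),      # bottom
    cbind(x0, ytop - t * H))          # left
  withr::with_seed(seed, {
    lapply(seq_len(n_roads), function(i) {
      e1 <- sample(4L, 1L)
      e2 <- sample(setdiff(1:4, e1), 1L)
      m <- rbind(edge_point(e1, stats::runif(1)),
                 edge_point(e2, stats::runif(1)))
      colnames(m) <- c("x", "y")
      m
    })
  })
}

#' Generate an urban mask from seeded population cores
#'
#' Gaussian density kernels around 1-3 core points (plus a little smoothed
#' noise) thresholded at a quantile: a stand-in for the census
#' people-per-square-mile core/fringe structure used to delineate urban
#' regions.
#'
#' @param shape Integer (rows, cols).
#' @param n_cores Number of urban cores.
#' @param urban_fraction Fraction of cells classified urban (quantile cut).
#' @param core_radius Kernel sd in metres.
#' @param seed Integer seed.
#' @param cell_size,origin Grid geometry.
#' @return Binary (0/1) `grid_raster`.
#' @export
generate_urban_mask <- function(shape, n_cores = 2, urban_fraction = 0.25,
                                core_radius = 900, seed = 1L, cell_size = 30,
                                origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  nr <- shape[1]; nc <- shape[2]
  g <- grid_raster(matrix(0, nr, nc), cell_size, origin)
  xy <- cell_xy(g, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  dens <- withr::with_seed(seed, {
    cores <- cbind(stats::runif(n_cores, origin[1] + 0.2 * nc * cell_size,
                                origin[1] + 0.8 * nc * cell_size),
                   stats::runif(n_cores, origin[2] - 0.8 * nr * cell_size,
                                origin[2] - 0.2 * nr * cell_size))
    d <- matrix(0, nr, nc)
    for (i in seq_len(n_cores)) {
      r2 <- (xy[, 1] - cores[i, 1])^2 + (xy[, 2] - cores[i, 2])^2
      d <- d + matrix(exp(-r2 / (2 * core_radius^2)), nr, nc)
    }
    d + 0.05 * gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 3)
  })
  cut <- stats::quantile(dens, 1 - urban_fraction, names = FALSE)
  g$values <- (dens > cut) + 0
  g
}

#' Generate a protected-areas mask of scattered discs
#'
#' @param shape Integer (rows, cols).
#' @param n_areas Number of protected polygons (discs).
#' @param radius_range Disc radius range in metres.
#' @param seed Integer seed.
#' @param cell_size,origin Grid geometry.
#' @return Binary (0/1) `grid_raster`.
#' @export
generate_protected_mask <- function(shape, n_areas = 4,
                                    radius_range = c(100, 300), seed = 1L,
                                    cell_size = 30, origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  nr <- shape[1]; nc <- shape[2]
  g <- grid_raster(matrix(0, nr, nc), cell_size, origin)
  if (n_areas == 0) return(g)
  xy <- cell_xy(g, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  g$values <- withr::with_seed(seed, {
    m <- matrix(0, nr, nc)
    for (i in seq_len(n_areas)) {
      ctr <- c(stats::runif(1, origin[1], origin[1] + nc * cell_size),
               stats::runif(1, origin[2] - nr * cell_size, origin[2]))
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      d2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
      m[matrix(d2, nr, nc) <= rad^2] <- 1
    }
    m
  })
  g
}

#' Generate a complete synthetic scene
#'
#' Bundles suitability, urban and protected masks, roads and per-species
#' occurrences on a shared grid. Sub-seeds for each component are derived
#' deterministically from `seed`.
#'
#' @param shape Integer (rows, cols).
#' @param species Character vector of species ids to sample occurrences for.
#' @param n_occurrences Points per species.
#' @param correlation_length Suitability autocorrelation scale (m).
#' @param planted_features Passed to [generate_suitability()].
#' @param n_roads,n_cores,n_protected Component counts.
#' @param sampling_exponent Habitat bias of occurrence sampling.
#' @param seed Integer master seed.
#' @param cell_size,origin Grid geometry.
#' @return List of class `synthetic_scene` with elements `suitability`,
#'   `urban_mask`, `protected_mask`, `roads`, `occurrences`, `seed`.
#' @export
synthetic_scene <- function(shape = c(60, 60), species = c("sp1", "sp2", "sp3"),
                            n_occurrences = 40, correlation_length = 300,
                            planted_features = list(), n_roads = 3,
                            n_cores = 2, n_protected = 4,
                            sampling_exponent = 2, seed = 1L,
                            cell_size = 30, origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  sub <- function(k) (as.integer(seed) * 101L + k) %% 2147483647L
  suit <- generate_suitability(shape, correlation_length, planted_features,
                               seed = sub(1L), cell_size = cell_size,
                               origin = origin)
  occ <- do.call(rbind, lapply(seq_along(species), function(i)
    sample_occurrences(suit, n_occurrences, species[i], sampling_exponent,
                       seed = sub(10L + i))))
  structure(list(
    suitability = suit,
    urban_mask = generate_urban_mask(shape, n_cores, seed = sub(2L),
                                     cell_size = cell_size, origin = origin),
    protected_mask = generate_protected_mask(shape, n_protected,
                                             seed = sub(3L),
                                             cell_size = cell_size,
                                             origin = origin),
    roads = generate_roads(shape, n_roads, seed = sub(4L),
                           cell_size = cell_size, origin = origin),
    occurrences = occ,
    seed = as.integer(seed)),
    class = "synthetic_scene")
}

#' Write a scene to plain-text files
#'
#' Rasters as Esri ASCII grids, occurrences as CSV, roads as GeoJSON.
#'
#' @param scene A `synthetic_scene`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(suitability = file.path(outdir, "suitability.asc"),
             urban_mask = file.path(outdir, "urban_mask.asc"),
             protected_mask = file.path(outdir, "protected_mask.asc"),
             occurrences = file.path(outdir, "occurrences.csv"),
             roads = file.path(outdir, "roads.geojson"))
  write_asc(scene$suitability, paths["suitability"])
  write_asc(scene$urban_mask, paths["urban_mask"])
  write_asc(scene$protected_mask, paths["protected_mask"])
  utils::write.csv(scene$occurrences, paths["occurrences"], row.names = FALSE)
  writeLines(roads_geojson(scene$roads), paths["roads"])
  invisible(paths)
}

roads_geojson <- function(roads) {
  feats <- lapply(seq_along(roads), function(i) list(
    type = "Feature",
    properties = list(road_id = i),
    geometry = list(type = "LineString",
                    coordinates = unname(lapply(seq_len(nrow(roads[[i]])),
                      function(r) as.numeric(roads[[i]][r, ]))))))
  jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                   auto_unbox = TRUE, digits = NA)
}
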