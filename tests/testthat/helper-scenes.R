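# Planted-feature scenes used for parameter-recovery checks. Geometry is
# fixed; only the background noise varies with the seed, so the planted
# structure is always the dominant feature by construction.

# low-suitability matrix crossed by one high-suitability corridor
corridor_recovery_scene <- function(seed, shape = c(40, 40)) {
  h <- shape[1] * 30
  mid_y <- -h / 2
  suit <- generate_suitability(shape, correlation_length = 300, seed = seed,
                               base_range = c(0, 0.1),
                               planted_features = list(
                                 list(type = "corridor", from = c(15, mid_y),
                                      to = c(shape[2] * 30 - 15, mid_y),
                                      width = 60, value = 1)))
  list(suitability = suit,
       resistance = suitability_to_resistance(suit, 0.7),
       corridor_cells = which(suit$values == 1))
}

# two habitat patches split by a zero-suitability wall on a suitable matrix
barrier_recovery_scene <- function(seed, shape = c(30, 30)) {
  w <- shape[2] * 30; h <- shape[1] * 30
  suit <- generate_suitability(shape, correlation_length = 300, seed = seed,
                               base_range = c(0.75, 0.95),
                               planted_features = list(
                                 list(type = "barrier",
                                      line = cbind(c(w / 2, w / 2), c(0, -h)),
                                      width = 60, value = 0)))
  habitat <- binarize(suit, 0.7)
  resistance <- suitability_to_resistance(suit, 0.7)
  patches <- label_patches(habitat)
  wall_cols <- unique(urbanlink:::index_to_cells(
    suit, which(suit$values == 0))[, 2])
  list(suitability = suit, resistance = resistance, patches = patches,
       wall_cols = wall_cols)
}

# two patches joined by one sub-threshold corridor: every species' LCP must
# use it, so the multi-species count on corridor cells reaches n_species
shared_corridor_scene <- function(seed, shape = c(40, 40), n_species = 3) {
  w <- shape[2] * 30; h <- shape[1] * 30
  feats <- list(
    list(type = "patch", center = c(0.12 * w, -h / 2), radius = 110,
         value = 0.95),
    list(type = "patch", center = c(0.88 * w, -h / 2), radius = 110,
         value = 0.95),
    list(type = "corridor", from = c(0.12 * w, -h / 2),
         to = c(0.88 * w, -h / 2), width = 45, value = 0.5))
  suit <- generate_suitability(shape, correlation_length = 300, seed = seed,
                               base_range = c(0, 0.1),
                               planted_features = feats)
  resistance <- suitability_to_resistance(suit, 0.8)
  patches <- label_patches(binarize(suit, 0.8))
  corridor_cells <- which(suit$values == 0.5)
  list(suitability = suit, resistance = resistance, patches = patches,
       corridor_cells = corridor_cells, n_species = n_species)
}
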