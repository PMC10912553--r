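#!/usr/bin/env Rscript
# Build the synthetic study landscape every later step analyses: a 60 x 60
# cell (1.8 km square, 30 m) autocorrelated suitability surface with an
# urban core, protected discs, three roads, and occurrences for three
# species sampled preferentially in suitable habitat.

library(urbanlink)

seed <- 2024L
outdir <- "results/scene"

scene <- synthetic_scene(
  shape = c(60, 60), species = c("turtle", "snake", "bee"),
  n_occurrences = 45, correlation_length = 300, n_roads = 3,
  n_cores = 2, n_protected = 4, sampling_exponent = 2, seed = seed)

paths <- write_scene(scene, outdir)

cat("Scene written to", outdir, "(seed", seed, ")\n")
cat(sprintf("  suitability range: %.3f - %.3f\n",
            min(scene$suitability$values), max(scene$suitability$values)))
cat(sprintf("  urban cover: %.1f%%  protected cover: %.1f%%\n",
            100 * mean(scene$urban_mask$values),
            100 * mean(scene$protected_mask$values)))
cat(sprintf("  %d occurrences across %d species, %d roads\n",
            nrow(scene$occurrences),
            length(unique(scene$occurrences$species_id)),
            length(scene$roads)))
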