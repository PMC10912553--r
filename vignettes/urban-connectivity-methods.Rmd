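---
title: "Methods: multi-species habitat connectivity on urban landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-species habitat connectivity on urban landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanlink)
```

`urbanlink` implements a complete multi-species, multi-tool habitat
connectivity analysis for rare species in urbanizing landscapes: from a
continuous habitat-suitability surface and species occurrence points to
binary habitat, species-specific resistance surfaces, least-cost patch
networks, circuit-theory current maps, corridors with pinch points and
barriers, landscape pattern metrics, and multi-species linkage summaries.
Because georeferenced occurrence data for rare species are routinely
withheld for species-protection reasons, the package ships a seeded
synthetic-landscape generator that reproduces the statistical structure such
an analysis assumes, and every stage is tested on those synthetic scenes.
This vignette explains the models, the parameters that matter, and the
numerical choices, in the order the pipeline runs.

## Rasters and coordinates

All surfaces live on a single square-cell grid (`grid_raster`): a numeric
matrix plus cell size (default 30 m, a typical land-cover resolution),
upper-left origin in projected metres, and `NA` for nodata. Raster I/O uses
the plain-text Esri ASCII grid format (`write_asc()` / `read_asc()`), which
any GIS reads; vector outputs (roads, analysis areas) are GeoJSON and CSV.

## Synthetic landscapes

`generate_suitability()` builds the suitability field as Gaussian-smoothed
white noise rescaled to [0, 1] — the simplest stationary autocorrelated
random field. The `correlation_length` (metres, default 300) is the sd of
the smoothing kernel; an exponential-variogram fit to sampled cell pairs
recovers the ordering of this parameter. Two caveats follow from the
construction and matter when reading test results:

* rescaling by the field's min/max skews the value distribution (a few
  extreme cells stretch the scale), so thresholded habitat fractions need
  not resemble the nominal quantiles of a uniform distribution;
* the field is stationary and isotropic — real urban suitability surfaces
  have land-cover discontinuities, anisotropic river/road structure and
  class-specific patch shapes. Passing tests show the estimators recover
  planted structure under controlled conditions, not that an urban SDM is
  well calibrated.

Planted features (`patch`, `corridor`, `barrier` descriptors) overwrite the
field after rescaling and are the package's validation surface: a planted
low-resistance corridor must attract circuit current, a planted wall must
attain the maximum barrier score, a planted shared corridor must reach the
full multi-species count. `generate_urban_mask()` thresholds a kernel
density around 1–3 seeded cores at a configurable quantile (default 25 %
urban cover, matching the smaller real urban analysis areas);
`generate_protected_mask()` scatters discs with 100–300 m radii, giving of
order 10–20 % protected cover. `sample_occurrences()` draws cells with
probability proportional to suitability^`sampling_exponent` (default 2) and
jitters points uniformly within the 30 m cell — sub-cell position carries no
information downstream. Every generator is a pure function of (parameters,
seed).

## Occurrence thinning and habitat thresholds

`thin_occurrences()` enforces a minimum spacing (default 1 km) greedily in
input order: a record is kept iff it is far enough from everything already
kept. The greedy order is a documented convention — the choice of *which* of
two close points survives is irreducibly arbitrary, and fixing it makes runs
reproducible. `adaptive_thin_occurrences()` halves the spacing until at
least `min_n` (default 20) records survive, the standard fallback for
species with limited distributions.

`msss_threshold()` converts continuous suitability to habitat at the cutoff
maximizing sensitivity + specificity over presence vs background scores
(equivalent to maximizing the true skill statistic). Candidates are the
unique observed scores; ties break toward the smallest candidate, which
retains the most habitat — conservative for rare species.
`presence_percentile_threshold()` implements the 10th-percentile presence
rule (linear-interpolation quantile, the common statistical default) used
when MSSS is too restrictive. `binarize()` maps suitability ≥ t to habitat.

`boyce_index()` checks calibration: moving-window predicted-to-expected
ratios F over the suitability range (101 windows, width a tenth of the
range — standard continuous-Boyce practice), Spearman-correlated against the
window midpoints. Windows with zero expected fraction are dropped and runs
of consecutive duplicate F are collapsed before correlating, without which a
perfectly calibrated model scores below 1. The index is noisy below ~100
presence points (sd ≈ 0.15 at n = 1000 uniform points on a 40 × 40 scene,
much larger at n ≈ 20), which is why the demo tables in `analysis/` show
unstable values for heavily thinned species while large-sample checks sit
near the +1/0/−1 anchors.

## Resistance surfaces

`suitability_to_resistance()` applies a negative-exponential decay anchored
at two published constants: resistance 1000 where suitability is 0 and
exactly 1 at or above the habitat threshold t:

R(h) = 1 + (R_max − 1) · [1 − (1 − e^(−k·min(h,t)/t)) / (1 − e^(−k))].

The source workflow cites this transform without printing its equation, so
the package adopts this form, which satisfies both printed anchors exactly
for every k, and defaults to k = 8 — a standard strongly-nonlinear shape in
the suitability-to-resistance literature (movement cost collapses quickly
once habitat becomes moderately suitable). As k → 0 the transform tends to
the linear ramp; both limits are tested. The anchors are set by assignment
after the formula evaluates, so they hold bit-exactly regardless of
floating-point residue.

Roads are buffered 30 m, rasterized by cell-centre distance to the
polylines, and mosaicked with taxon costs (1000 reptiles, 500 bird/bat, 250
bees) under a `max(resistance, cost)` rule. Overwriting instead of
maximizing was the open alternative; max was chosen so a low road cost can
never *improve* a cell that the habitat model already rates worse — this
matters only for the bee surfaces, and the choice is configurable by
editing the mosaicking step.

## Patches and the habitat network

`label_patches()` extracts connected components of the binary habitat under
8-neighbour adjacency (diagonal contact counts, the common habitat-patch
convention; 4-neighbour is switchable). The minimum viable patch area comes
either from a published value (`species_profile()`) or from
`min_patch_from_occupied()`: one area record per occurrence that falls in a
patch, drop the smallest 20 % of records, return the smallest retained
area. Records (not unique patches) are used because the rule parallels the
10th-percentile treatment of occurrence records: heavily occupied patches
should weigh more.

`cost_distance()` runs Dijkstra over the grid graph: moves to 8 neighbours,
edge cost = mean of the two cell resistances × centre distance (cell size,
×√2 diagonally). Under uniform resistance 1, cost equals metric distance,
which is the convention that lets dispersal distances reported in km be used
directly as cost thresholds. Patch-to-patch distances are minima over
boundary-cell pairs (LCP software semantics), implemented with zero-cost
virtual super-nodes so one shortest-path query handles a whole patch.

`build_graph()` links *all* patch pairs regardless of distance — the
dispersal kernel, not a hard cutoff, discounts long links. The kernel
p(d) = exp(−αd) is calibrated so p(median dispersal) = 0.5.
`pc_index()` computes the Probability of Connectivity
PC = Σᵢⱼ aᵢaⱼp*ᵢⱼ / A_L², with p*ᵢⱼ the best multi-link route probability
(shortest path on −log p weights) and A_L the full landscape area.
`dpc()` removes each patch in turn (dPC_k as a percentage of PC) and splits
it exactly into intra (own area), flux (dispersal to/from the patch) and
connector (stepping-stone role; zero for patches on no optimal route). The
decomposition identity is enforced to 1e-9 in tests, against exhaustive
path-enumeration oracles on small graphs.

## Circuit-theory current

`solve_pair_current()` treats the grid as a resistor network (conductance =
1 / (mean cell resistance × centre distance)), injects 1 A and solves
Kirchhoff's equations as a sparse symmetric system (Matrix Cholesky, one
factorization reused across injection pairs via a fixed reference node —
currents are independent of the reference). Cell current density is half
the sum of absolute incident edge currents, with terminal cells carrying the
full current through them. Voltages are verified against dense solves to
1e-10 and current conservation holds to 1e-8.

`peripheral_current_map()` avoids the injection-point artifact: the surface
is padded with a buffer ring (width 20 % of the larger grid dimension,
resistance = mean finite interior resistance), injection nodes are spaced
evenly along the outer ring (default 16, all 120 pairs), and the buffer is
clipped from the returned mean current map. The original tool chain does not
publish its ring settings; these defaults are the package's own, chosen so
the buffer is wide enough that ring geometry does not imprint on the
interior (verified by the no-interior-spike test on uniform surfaces), and
all are configurable.

## Corridors, pinch points, barriers

`normalized_corridor()` computes NC(x) = CWD_i(x) + CWD_j(x) − d_ij — the
detour cost of forcing the i–j route through x, zero exactly on the
least-cost path. The corridor mask keeps NC ≤ cutoff; the upstream tool's
default width is not a published number, so the cutoff is an explicit
parameter (default 2 × 10⁵ cost units ≈ 200 m of worst-case resistance-1000
matrix). Pair selection for corridor mapping uses the species' *maximum*
dispersal distance (2 km for the two 1-km-median reptiles with published
maxima; equal to the median otherwise).

`pinch_points()` makes everything outside the corridor mask non-conductive
and runs the pair circuit solve; a narrow neck carrying most of the 1 A is a
vulnerable linkage. `barrier_scan()` slides a circular restoration window
(resistance → 1 inside), recomputes all pairwise least-cost distances, and
scores the best improvement per metre of window diameter; scores are
verified against brute-force per-window recomputation.

## Landscape metrics

`clumpiness()` implements the aggregation metric on 4-neighbour,
double-counted adjacencies among raster-interior pairs (the "no border"
convention): G = like-adjacency share of habitat adjacencies, P = habitat
proportion, CLUMPY = (G−P)/(1−P) for G ≥ P or P ≥ 0.5, otherwise (G−P)/P.
Checkerboard → −1, random → ≈0, solid block → positive; the metric is
insensitive to habitat abundance. `connectance()` is the percentage of
patch pairs whose nearest boundary-cell centres lie within the species'
dispersal threshold; cell-centre distance is grid-native and unambiguous at
30 m, and the metric is monotone in the threshold.

## Sites, composition, multi-species linkages

`cluster_occurrences()` single-links points closer than twice the 5 km
buffer (< 10 km nearest-neighbour separation ⇔ overlapping buffers);
`delineate_area()` accepts clusters with at least 3 distinct species (2 in
the large-diverse-region mode) and returns the convex hull buffered by 5 km
— computed planar as the hull of 72-gon discs, accurate to ~0.1 % of the
disc area. `composition_report()` overlays cell centres against the polygon
and tabulates site area, urban/protected shares, and per-species habitat
shares. `rasterize_lcps()` + `sum_species()` produce the multi-species
linkage map: per-species binary LCP coverage (a cell crossed by many paths
of one species counts once — the map counts species, not paths) summed
across species. Exact 30 m overlap under-detects broad shared corridors;
a tolerance buffer would be the natural extension and is deliberately not
applied.

## Problem sizes and determinism

The shipped analyses and tests run on 30–60 cell square scenes with 12–16
peripheral nodes, barrier strides of 2–5 cells, and ≤ 7-patch graphs —
sizes at which every brute-force oracle (path enumeration, dense circuit
solves, per-window barrier recomputation) is computable, which is what makes
the dual-route checks meaningful. All stochastic stages take explicit seeds
and are bit-reproducible; `run_site()` derives per-stage sub-seeds from one
master seed and writes a manifest of every artifact.

## Known limitations

* Suitability modelling itself (SDM fitting, variable screening, ensemble
  weighting) is out of scope: the pipeline starts from a continuous
  suitability surface, synthetic or supplied.
* Distances, hulls and buffers are planar; inputs are assumed projected.
* The patch graph is complete; very large patch counts (hundreds) would
  need link thinning, which is not implemented.
* Barrier scanning recomputes pairwise Dijkstra per window — exact but
  quadratic-ish; at the shipped scene sizes this is seconds, not hours.
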