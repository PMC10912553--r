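test_that("thinning enforces spacing, maximality and idempotence", {
  # two points 500 m apart at a 1 km rule: one survives
  two <- occurrence_set("s", c(0, 500), c(0, 0))
  expect_equal(nrow(thin_occurrences(two, 1000)), 1L)
  # spacing 0 is the identity
  expect_identical(thin_occurrences(two, 0), two)
  # 5 collinear points at 600 m: greedy keeps positions 1, 3, 5
  five <- occurrence_set("s", seq(0, 2400, by = 600), 0)
  expect_equal(thin_occurrences(five, 1000)$x, c(0, 1200, 2400))
  # random clouds: output spacing holds, thinning is idempotent, subset
  for (seed in 1:5) {
    set.seed(seed)
    occ <- occurrence_set("s", runif(40, 0, 5000), runif(40, 0, 5000))
    th <- thin_occurrences(occ, 800)
    d <- as.matrix(dist(cbind(th$x, th$y)))
    expect_true(all(d[upper.tri(d)] >= 800))
    expect_identical(thin_occurrences(th, 800), th)
    expect_true(all(th$x %in% occ$x))
  }
  expect_equal(nrow(thin_occurrences(occurrence_set(), 1000)), 0L)
})

test_that("adaptive thinning relaxes spacing only for sparse species", {
  set.seed(12)
  dense <- occurrence_set("d", runif(200, 0, 20000), runif(200, 0, 20000))
  th <- adaptive_thin_occurrences(dense, 1000, min_n = 20)
  expect_equal(attr(th, "spacing"), 1000)   # plenty of spread records
  expect_gte(nrow(th), 20)
  sparse <- occurrence_set("s", runif(60, 0, 1200), runif(60, 0, 1200))
  th2 <- adaptive_thin_occurrences(sparse, 1000, min_n = 20)
  expect_lt(attr(th2, "spacing"), 1000)     # spacing relaxed
  expect_gte(nrow(th2), 20)
  d <- as.matrix(dist(cbind(th2$x, th2$y)))
  expect_true(all(d[upper.tri(d)] >= attr(th2, "spacing")))
})

test_that("MSSS picks the smallest maximizer of sensitivity + specificity", {
  r <- msss_threshold(c(0.9, 0.8, 0.4), c(0.3, 0.2, 0.1))
  expect_equal(r$threshold, 0.4)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # perfect separation reaches sens + spec = 2
  sep <- msss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$sensitivity + sep$specificity, 2)
  # identical lists: no separation, smallest candidate returned
  same <- msss_threshold(c(0.2, 0.5), c(0.2, 0.5))
  expect_equal(same$threshold, 0.2)
  expect_equal(same$sensitivity + same$specificity, 1)
})

test_that("MSSS equals brute-force maximization over a dense grid", {
  for (seed in 1:8) {
    set.seed(seed)
    pres <- round(runif(25), 3)
    bg <- round(runif(40), 3)
    r <- msss_threshold(pres, bg)
    grid <- seq(0, 1, by = 1e-4)
    ss <- vapply(grid, function(t) mean(pres >= t) + mean(bg < t), 0)
    expect_equal(r$sensitivity + r$specificity, max(ss), tolerance = 1e-12)
  }
})

test_that("presence-percentile threshold is the interpolated quantile", {
  sc <- seq(0.1, 1, by = 0.1)
  expect_equal(presence_percentile_threshold(sc, 0)$threshold, 0.1)
  expect_equal(presence_percentile_threshold(sc, 100)$threshold, 1)
  expect_equal(presence_percentile_threshold(sc, 10)$threshold, 0.19)
  expect_error(presence_percentile_threshold(numeric(0)), "non-empty")
})

test_that("binarize thresholds at >= t and propagates NA", {
  v <- matrix(c(0.2, 0.5, 0.8, NA, 0.5, 0.1, 0.9, 0.4, 0.6), 3, 3)
  g <- grid_raster(v)
  b <- binarize(g, 0.5)
  expect_equal(b$values[1, ], c(0, NA, 1))
  expect_equal(b$values[2, ], c(1, 1, 0))
  expect_true(all(binarize(g, 0)$values == 1, na.rm = TRUE))
  expect_true(all(binarize(g, 0.95)$values == 0, na.rm = TRUE))
  expect_true(is.na(b$values[1, 2]))
})

test_that("thresholding perfectly separated scores keeps all presences", {
  suit <- grid_raster(matrix(seq(0, 1, length.out = 100), 10, 10))
  pres <- suit$values[suit$values > 0.7]
  bg <- suit$values[suit$values < 0.5]
  t <- msss_threshold(pres, bg)
  hab <- binarize(suit, t)
  expect_true(all(hab$values[suit$values %in% pres] == 1))
})

test_that("Boyce index hits the +/-1 bounds on monotone constructions", {
  suit <- grid_raster(matrix(seq(0, 1, length.out = 1600), 40, 40))
  cells_at <- function(cond) {
    idx <- which(cond)
    rc <- cbind(((idx - 1) %% 40) + 1, ((idx - 1) %/% 40) + 1)
    xy <- cell_xy(suit, rc[, 1], rc[, 2])
    occurrence_set("s", xy[, 1], xy[, 2])
  }
  top <- boyce_index(suit, cells_at(suit$values >= 0.9))
  expect_equal(top$index, 1)
  bottom <- boyce_index(suit, cells_at(suit$values <= 0.1))
  expect_equal(bottom$index, -1)
})

test_that("Boyce index is near zero for uniform random presences", {
  suit <- generate_suitability(c(40, 40), 300, seed = 14)
  set.seed(21)
  idx <- sample(1600, 1000, replace = TRUE)
  rc <- cbind(((idx - 1) %% 40) + 1, ((idx - 1) %/% 40) + 1)
  xy <- cell_xy(suit, rc[, 1], rc[, 2])
  b <- boyce_index(suit, occurrence_set("s", xy[, 1], xy[, 2]))
  expect_lt(abs(b$index), 0.3)
})

test_that("Boyce errors when presences miss the raster", {
  suit <- generate_suitability(c(20, 20), 300, seed = 1)
  far <- occurrence_set("s", 1e6, 1e6)
  expect_error(boyce_index(suit, far), "outside")
})
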