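test_that("normalized corridors are zero exactly on the optimal path", {
  set.seed(3)
  v <- matrix(runif(100, 1, 50), 10, 10)
  r <- grid_raster(v)
  pi <- cbind(5, 1); pj <- cbind(5, 10)
  corr <- normalized_corridor(r, pi, pj, cutoff = Inf)
  lcp <- cost_distance(r, pi, pj)
  expect_equal(min(corr$nc$values), 0)
  expect_true(all(corr$nc$values[lcp$path] < 1e-9))
  expect_true(all(corr$nc$values >= 0))
  # NC decomposes as CWD_i + CWD_j - d_ij (checked against the BF oracle)
  ref_i <- oracle_bellman_ford(v, urbanlink:::cells_to_index(r, pi))
  ref_j <- oracle_bellman_ford(v, urbanlink:::cells_to_index(r, pj))
  expect_equal(as.numeric(corr$nc$values),
               ref_i + ref_j - lcp$distance, tolerance = 1e-9)
})

test_that("cells behind an infinite wall are excluded from corridors", {
  v <- matrix(1, 7, 7); v[, 4] <- Inf; v[4, 4] <- 1
  r <- grid_raster(v)
  corr <- normalized_corridor(r, cbind(4, 1), cbind(4, 7), cutoff = 1e5)
  expect_false(corr$empty)
  expect_true(all(corr$mask$values[is.na(corr$nc$values)] == 0))
  # fully walled-off pair is flagged empty
  v2 <- matrix(1, 7, 7); v2[, 4] <- Inf
  corr2 <- normalized_corridor(grid_raster(v2), cbind(4, 1), cbind(4, 7))
  expect_true(corr2$empty)
})

test_that("pinch points carry the full current through a 1-cell neck", {
  v <- matrix(1, 7, 9)
  v[, 5] <- Inf; v[4, 5] <- 1     # neck
  r <- grid_raster(v)
  corr <- normalized_corridor(r, cbind(1:7, 1), cbind(1:7, 9), cutoff = Inf)
  pm <- pinch_points(r, corr, cbind(1:7, 1), cbind(1:7, 9))
  expect_equal(max(pm$current$values), pm$current$values[4, 5])
  expect_equal(pm$current$values[4, 5], 1, tolerance = 1e-8)
  # a uniformly wide corridor never concentrates the full ampere
  r2 <- uniform_resistance(7, 9)
  corr2 <- normalized_corridor(r2, cbind(1:7, 1), cbind(1:7, 9), cutoff = Inf)
  pm2 <- pinch_points(r2, corr2, cbind(1:7, 1), cbind(1:7, 9))
  interior <- pm2$current$values[, 2:8]
  expect_lt(max(interior), 1)
})

test_that("two disjoint equal branches each carry half the current", {
  v <- matrix(Inf, 5, 9)
  v[1, ] <- 1; v[5, ] <- 1        # two disjoint horizontal branches
  v[1:5, 1] <- 1; v[1:5, 9] <- 1  # terminal columns join them
  r <- grid_raster(v)
  corr <- normalized_corridor(r, cbind(1:5, 1), cbind(1:5, 9), cutoff = Inf,
                              neighbors = 4)
  pm <- pinch_points(r, corr, cbind(1:5, 1), cbind(1:5, 9), neighbors = 4)
  expect_equal(pm$current$values[1, 5], 0.5, tolerance = 1e-8)
  expect_equal(pm$current$values[5, 5], 0.5, tolerance = 1e-8)
})

test_that("pinch analysis rejects corridors that sever the pair", {
  v <- matrix(1, 5, 5)
  r <- grid_raster(v)
  corr <- normalized_corridor(r, cbind(3, 1), cbind(3, 5), cutoff = Inf)
  corr$mask$values[, 3] <- 0       # cut the corridor by hand
  expect_error(pinch_points(r, corr, cbind(3, 1), cbind(3, 5)),
               "disconnects")
})

test_that("barrier scores are non-negative and zero on restored ground", {
  v <- matrix(1, 9, 9)
  hab <- matrix(0, 9, 9); hab[4:6, 1] <- 1; hab[4:6, 9] <- 1
  p <- label_patches(grid_raster(hab))
  bs <- barrier_scan(grid_raster(v), p, radius = 60, stride = 2)
  expect_true(all(bs$scores$values == 0))   # already minimal everywhere
})

test_that("a planted wall attains the maximum barrier score", {
  sc <- barrier_recovery_scene(seed = 2)
  bs <- barrier_scan(sc$resistance, sc$patches, radius = 90, stride = 2)
  expect_gt(max(bs$scores$values), 0)
  best <- which(bs$scores$values == max(bs$scores$values), arr.ind = TRUE)
  # every maximal window centre lies within one window radius of the wall
  expect_true(all(abs(best[, "col"] - mean(sc$wall_cols)) <= 3 + 1e-9))
})

test_that("barrier scores equal per-window recomputation by the oracle", {
  set.seed(17)
  v <- matrix(runif(225, 1, 500), 15, 15)
  hab <- matrix(0, 15, 15); hab[7:9, 1:2] <- 1; hab[7:9, 14:15] <- 1
  p <- label_patches(grid_raster(hab))
  r <- grid_raster(v)
  radius <- 60; stride <- 4
  bs <- barrier_scan(r, p, radius = radius, stride = stride)
  src <- urbanlink:::cells_to_index(r, p$patches[[1]]$cells)
  tgt <- urbanlink:::cells_to_index(r, p$patches[[2]]$cells)
  base <- min(oracle_bellman_ford(v, src)[tgt])
  for (cr in seq(1, 15, stride)) for (cc in seq(1, 15, stride)) {
    v2 <- v
    disc <- outer(seq_len(15), seq_len(15),
                  function(i, j) (i - cr)^2 + (j - cc)^2 <= (radius / 30)^2)
    v2[disc] <- 1
    restored <- min(oracle_bellman_ford(v2, src)[tgt])
    expect_equal(bs$scores$values[cr, cc],
                 max(base - restored, 0) / (2 * radius), tolerance = 1e-9)
  }
})
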