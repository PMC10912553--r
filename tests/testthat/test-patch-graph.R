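test_that("dispersal kernel is calibrated at the median distance", {
  k <- dispersal_kernel(1000)
  expect_equal(exp(-k$alpha * 1000), 0.5)
  expect_error(dispersal_kernel(0), "d_med")
})

test_that("the patch graph is complete and symmetric", {
  v <- matrix(0, 10, 14)
  v[2:3, 2:3] <- 1; v[8:9, 2:3] <- 1; v[5, 12:13] <- 1
  hab <- grid_raster(v)
  res <- uniform_resistance(10, 14)
  p <- label_patches(hab)
  g <- build_graph(p, res)
  expect_equal(nrow(g$edges), 3L)           # complete over 3 patches
  expect_length(build_graph(label_patches(grid_raster(
    matrix(c(1, rep(0, 399)), 20, 20))), uniform_resistance(20, 20))$edges$d,
    0L)
  # distances match direct pairwise recomputation (symmetry built in)
  for (k in seq_len(nrow(g$edges))) {
    i <- match(g$edges$i[k], g$nodes$id)
    j <- match(g$edges$j[k], g$nodes$id)
    expect_equal(
      g$edges$d[k],
      cost_distance(res, p$patches[[j]]$cells, p$patches[[i]]$cells)$distance)
  }
})

test_that("least-cost links route through a planted gap", {
  v <- matrix(1, 11, 11)
  v[, 6] <- Inf
  v[6, 6] <- 1                       # single gap in the wall
  r <- grid_raster(v)
  hab <- matrix(0, 11, 11); hab[5:7, 1] <- 1; hab[5:7, 11] <- 1
  p <- label_patches(grid_raster(hab))
  g <- build_graph(p, r)
  path <- g$paths[[1]]
  expect_true(any(path[, 1] == 6 & path[, 2] == 6))
})

test_that("PC closed forms hold for one and two patches", {
  kern <- dispersal_kernel(1000)
  one <- toy_patch_graph(50, matrix(0, 1, 1), A_L = 200)
  expect_equal(pc_index(one, kern), 50^2 / 200^2)
  d12 <- 800
  two <- toy_patch_graph(c(30, 60), rbind(c(0, d12), c(d12, 0)), A_L = 300)
  p12 <- exp(-kern$alpha * d12)
  expect_equal(pc_index(two, kern),
               (30^2 + 60^2 + 2 * 30 * 60 * p12) / 300^2)
})

test_that("max-product path probabilities match exhaustive enumeration", {
  kern <- dispersal_kernel(500)
  for (seed in 1:6) {
    set.seed(seed)
    n <- 5
    pts <- matrix(runif(2 * n, 0, 3000), n, 2)
    dmat <- as.matrix(dist(pts))
    g <- toy_patch_graph(runif(n, 1, 20), dmat, A_L = 500)
    dp <- urbanlink:::dispersal_probabilities(g, kern)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(dp$pstar[i, j], oracle_max_product(dp$p, i, j),
                   tolerance = 1e-10)
      expect_gte(dp$pstar[i, j], dp$p[i, j])   # a route can only improve
    }
  }
})

test_that("dPC matches brute-force node removal and sums exactly", {
  kern <- dispersal_kernel(700)
  # 4-node line graph with known geometry
  dmat <- as.matrix(dist(cbind(c(0, 1000, 2000, 3000), 0)))
  areas <- c(5, 1, 1, 8)
  g <- toy_patch_graph(areas, dmat, A_L = 100)
  res <- dpc(g, kern)
  dp <- urbanlink:::dispersal_probabilities(g, kern)
  PC <- oracle_pc(areas, dp$p, 100)
  expect_equal(pc_index(g, kern), PC, tolerance = 1e-12)
  for (k in 1:4) {
    PC_wo <- oracle_pc(areas[-k], dp$p[-k, -k, drop = FALSE], 100)
    expect_equal(res$dPC[k], 100 * (PC - PC_wo) / PC, tolerance = 1e-9)
  }
  expect_equal(res$dPC, res$dPCintra + res$dPCflux + res$dPCconnector,
               tolerance = 1e-9)
  # random graphs: decomposition identity and non-negative dPC
  for (seed in 1:4) {
    set.seed(seed)
    n <- 6
    dmat <- as.matrix(dist(matrix(runif(2 * n, 0, 4000), n, 2)))
    g2 <- toy_patch_graph(runif(n, 1, 30), dmat, A_L = 400)
    r2 <- dpc(g2, kern)
    expect_equal(r2$dPC, r2$dPCintra + r2$dPCflux + r2$dPCconnector,
                 tolerance = 1e-9)
    expect_true(all(r2$dPC >= -1e-9))
  }
})

test_that("a sole patch scores dPC = 100 and stepping stones score 0", {
  kern <- dispersal_kernel(1000)
  one <- toy_patch_graph(10, matrix(0, 1, 1), A_L = 50)
  expect_equal(dpc(one, kern)$dPC, 100)
  # triangle where the third node is never on an optimal route
  dmat <- rbind(c(0, 100, 5000), c(100, 0, 5000), c(5000, 5000, 0))
  g <- toy_patch_graph(c(5, 5, 5), dmat, A_L = 100)
  res <- dpc(g, kern)
  expect_equal(res$dPCconnector[3], 0, tolerance = 1e-9)
})

test_that("removing an isolated zero-area node leaves PC unchanged", {
  kern <- dispersal_kernel(800)
  dmat <- rbind(c(0, 500, Inf), c(500, 0, Inf), c(Inf, Inf, 0))
  with_iso <- toy_patch_graph(c(10, 20, 0), dmat, A_L = 200)
  without <- toy_patch_graph(c(10, 20), dmat[1:2, 1:2], A_L = 200)
  expect_equal(pc_index(with_iso, kern), pc_index(without, kern))
})
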