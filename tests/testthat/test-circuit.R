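test_that("series and parallel circuits split current exactly", {
  chain <- uniform_resistance(1, 3)
  cm <- solve_pair_current(chain, cbind(1, 1), cbind(1, 3))
  expect_equal(as.numeric(cm$current$values), c(1, 1, 1))   # series: 1 A
  expect_equal(cm$effective_resistance, 60)   # two 30-unit resistors
  # two identical parallel branches around a blocked centre
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  ring <- grid_raster(v)
  cm2 <- solve_pair_current(ring, cbind(2, 1), cbind(2, 3), neighbors = 4)
  expect_equal(cm2$current$values[1, 2], 0.5)
  expect_equal(cm2$current$values[3, 2], 0.5)
  expect_equal(cm2$current$values[2, 1], 1)
})

test_that("voltages match a dense solve of the Kirchhoff system", {
  for (seed in 1:4) {
    set.seed(seed)
    v <- matrix(runif(9, 1, 50), 3, 3)
    r <- grid_raster(v)
    cm <- solve_pair_current(r, cbind(1, 1), cbind(3, 3))
    ref <- oracle_circuit_voltages(v, 1, 9)
    expect_equal(as.numeric(cm$voltage$values), ref, tolerance = 1e-10)
  }
})

test_that("current is conserved at every non-terminal node", {
  set.seed(5)
  v <- matrix(runif(49, 1, 200), 7, 7)
  r <- grid_raster(v)
  cm <- solve_pair_current(r, cbind(1, 1), cbind(7, 7))
  e <- oracle_edges(v)
  volt <- as.numeric(cm$voltage$values)
  net <- rep(0, 49)
  for (k in seq_len(nrow(e))) {
    I <- (volt[e[k, 1]] - volt[e[k, 2]]) / e[k, 3]
    net[e[k, 1]] <- net[e[k, 1]] - I
    net[e[k, 2]] <- net[e[k, 2]] + I
  }
  expect_true(all(abs(net[-c(1, 49)]) < 1e-8))
  expect_equal(net[1], -1, tolerance = 1e-8)   # 1 A injected
  expect_equal(net[49], 1, tolerance = 1e-8)
})

test_that("effective resistance of a 1D chain is the series sum", {
  set.seed(8)
  res <- runif(6, 1, 100)
  r <- grid_raster(matrix(res, 1, 6))
  cm <- solve_pair_current(r, cbind(1, 1), cbind(1, 6))
  expected <- sum((res[-6] + res[-1]) / 2 * 30)
  expect_equal(cm$effective_resistance, expected, tolerance = 1e-10)
})

test_that("scaling all resistances rescales voltage but not current", {
  set.seed(11)
  v <- matrix(runif(36, 1, 300), 6, 6)
  a <- solve_pair_current(grid_raster(v), cbind(1, 1), cbind(6, 6))
  b <- solve_pair_current(grid_raster(2 * v), cbind(1, 1), cbind(6, 6))
  expect_equal(b$current$values, a$current$values, tolerance = 1e-9)
  expect_equal(b$voltage$values, 2 * a$voltage$values, tolerance = 1e-9)
})

test_that("disconnected terminals are reported", {
  v <- matrix(1, 5, 5); v[, 3] <- NA
  expect_error(solve_pair_current(grid_raster(v), cbind(3, 1), cbind(3, 5)),
               "no conductive path")
})

test_that("multi-cell terminals are tied to one potential", {
  r <- uniform_resistance(5, 9)
  cm <- solve_pair_current(r, cbind(1:5, 1), cbind(1:5, 9))
  vs <- unique(round(cm$voltage$values[, 1], 12))
  expect_length(vs, 1L)
  # total injected current still 1 A: column 5 carries it all
  mid <- cm$current$values[, 5]
  expect_equal(sum(mid), 1, tolerance = 1e-8)
})

test_that("peripheral maps avoid node artifacts on uniform surfaces", {
  r <- uniform_resistance(25, 25, value = 10)
  cm <- peripheral_current_map(r, peripheral_ring(n_nodes = 12))
  cur <- cm$current$values
  expect_true(all(is.finite(cur)))
  expect_true(all(cur >= 0))
  expect_lt(max(cur), 2 * stats::median(cur))   # no injection spikes inside
  expect_equal(cm$n_pairs, choose(12, 2))
})

test_that("two opposite peripheral nodes give a symmetric field", {
  # on a square grid, m = 2 places the nodes at opposite corners, so the
  # field is symmetric about the node axis (the main diagonal)
  r <- uniform_resistance(21, 21)
  cm <- peripheral_current_map(r, peripheral_ring(n_nodes = 2))
  cur <- cm$current$values
  expect_equal(cur, t(cur), tolerance = 1e-6)
})

test_that("a planted low-resistance corridor concentrates current", {
  sc <- corridor_recovery_scene(seed = 3)
  cm <- peripheral_current_map(sc$resistance, peripheral_ring(n_nodes = 12))
  cur <- cm$current$values
  top <- stats::quantile(cur, 0.9)
  expect_true(all(cur[sc$corridor_cells] >= top))
})

test_that("sampled pair schemes are seeded and smaller", {
  r <- uniform_resistance(20, 20)
  a <- peripheral_current_map(r, peripheral_ring(n_nodes = 10),
                              pair_scheme = "sampled", n_pairs = 10, seed = 4)
  b <- peripheral_current_map(r, peripheral_ring(n_nodes = 10),
                              pair_scheme = "sampled", n_pairs = 10, seed = 4)
  expect_equal(a$n_pairs, 10)
  expect_identical(a$current$values, b$current$values)
})
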