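test_that("generators are pure functions of parameters and seed", {
  a <- generate_suitability(c(25, 30), 300, seed = 4)
  b <- generate_suitability(c(25, 30), 300, seed = 4)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0 & a$values <= 1))
  r1 <- generate_roads(c(25, 30), 3, seed = 9)
  r2 <- generate_roads(c(25, 30), 3, seed = 9)
  expect_identical(r1, r2)
  s1 <- synthetic_scene(shape = c(25, 25), seed = 12)
  s2 <- synthetic_scene(shape = c(25, 25), seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(a$values,
                         generate_suitability(c(25, 30), 300, seed = 5)$values))
})

test_that("degenerate shapes are rejected", {
  expect_error(generate_suitability(c(1, 40), 300), "2 cells")
  expect_error(generate_suitability(c(10, 40), 300), "20 x 20")
})

test_that("planted features shape the surface as described", {
  suit <- generate_suitability(
    c(30, 30), 300, seed = 2,
    planted_features = list(
      list(type = "barrier", line = cbind(c(450, 450), c(0, -900)),
           width = 60, value = 0.01),
      list(type = "patch", center = c(150, -150), radius = 90, value = 0.97)))
  band <- abs(cell_xy(suit, rep(1:30, 30), rep(1:30, each = 30))[, "x"] -
                450) <= 30
  expect_true(all(suit$values[matrix(band, 30, 30)] < 0.05))
  rc <- xy_cell(suit, 150, -150)
  expect_gte(suit$values[rc], 0.97)
})

test_that("longer correlation length gives a longer variogram range", {
  fit_range <- function(cl) {
    s <- generate_suitability(c(60, 60), cl, seed = 31)
    v <- s$values
    set.seed(99)
    i <- cbind(sample(60, 4000, TRUE), sample(60, 4000, TRUE))
    j <- cbind(sample(60, 4000, TRUE), sample(60, 4000, TRUE))
    d <- sqrt(rowSums((i - j)^2)) * 30
    gamma <- (v[i] - v[j])^2 / 2
    keep <- d > 0 & d < 1200
    bins <- cut(d[keep], seq(0, 1200, 60))
    emp <- tapply(gamma[keep], bins, mean)
    mid <- seq(30, 1170, 60)[!is.na(emp)]
    emp <- emp[!is.na(emp)]
    fit <- stats::nls(emp ~ s0 * (1 - exp(-mid / a)),
                      start = list(s0 = max(emp), a = 200),
                      control = list(warnOnly = TRUE))
    coef(fit)[["a"]]
  }
  expect_gt(fit_range(300), fit_range(30))
})

test_that("occurrence sampling tracks suitability with the exponent", {
  suit <- generate_suitability(c(40, 40), 300, seed = 6)
  mu <- mean(suit$values)
  occ0 <- sample_occurrences(suit, 2000, "s", sampling_exponent = 0, seed = 1)
  rc <- xy_cell(suit, occ0$x, occ0$y)
  expect_equal(mean(suit$values[rc]), mu, tolerance = 0.05)
  occ2 <- sample_occurrences(suit, 500, "s", sampling_exponent = 2, seed = 1)
  rc2 <- xy_cell(suit, occ2$x, occ2$y)
  expect_gt(mean(suit$values[rc2]), mu)
  expect_equal(nrow(sample_occurrences(suit, 1, "s", seed = 3)), 1L)
  zero <- grid_raster(matrix(0, 20, 20))
  expect_error(sample_occurrences(zero, 5, "s"), "support")
})

test_that("habitat bias is systematic across seeds", {
  suit <- generate_suitability(c(30, 30), 300, seed = 8)
  mu <- mean(suit$values)
  diffs <- vapply(1:100, function(s) {
    occ <- sample_occurrences(suit, 50, "s", sampling_exponent = 2, seed = s)
    mean(suit$values[xy_cell(suit, occ$x, occ$y)]) - mu
  }, 0)
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("roads cross the extent and respect n_roads", {
  expect_identical(generate_roads(c(25, 25), 0), list())
  roads <- generate_roads(c(25, 25), 3, seed = 5)
  expect_length(roads, 3L)
  on_boundary <- function(pt) {
    pt <- unname(pt)
    isTRUE(all.equal(pt[1], 0)) || isTRUE(all.equal(pt[1], 750)) ||
      isTRUE(all.equal(pt[2], 0)) || isTRUE(all.equal(pt[2], -750))
  }
  for (r in roads) {
    expect_true(on_boundary(r[1, ]))
    expect_true(on_boundary(r[2, ]))
    expect_false(isTRUE(all.equal(r[1, ], r[2, ])))
  }
})

test_that("scene components align and occurrences stay inside the extent", {
  sc <- synthetic_scene(shape = c(25, 30), seed = 3)
  expect_true(same_geometry(sc$suitability, sc$urban_mask))
  expect_true(same_geometry(sc$suitability, sc$protected_mask))
  rc <- xy_cell(sc$suitability, sc$occurrences$x, sc$occurrences$y)
  expect_false(anyNA(rc))
  expect_setequal(unique(sc$occurrences$species_id), c("sp1", "sp2", "sp3"))
  # urban mask is binary with the requested approximate coverage
  expect_true(all(sc$urban_mask$values %in% 0:1))
  expect_equal(mean(sc$urban_mask$values), 0.25, tolerance = 0.02)
})

test_that("scene files round-trip through plain-text formats", {
  sc <- synthetic_scene(shape = c(22, 22), seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  suit <- read_asc(paths[["suitability"]])
  expect_equal(suit$values, sc$suitability$values, tolerance = 1e-8)
  occ <- read.csv(paths[["occurrences"]])
  expect_equal(nrow(occ), nrow(sc$occurrences))
  gj <- jsonlite::fromJSON(paths[["roads"]], simplifyVector = FALSE)
  expect_length(gj$features, length(sc$roads))
})
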