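test_that("classify_ground passes pre-classified flags through unchanged", {
  pc <- point_cloud(1:4, 1:4, c(0, 10, 0, 12),
                    ground = c(TRUE, FALSE, TRUE, FALSE))
  out <- classify_ground(pc)
  expect_identical(out$ground, pc$ground)
})

test_that("minimum-grid classifier separates flat terrain from trees", {
  g <- expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5))
  trees <- withr::with_seed(1, data.frame(x = runif(100, 2, 8),
                                          y = runif(100, 2, 8),
                                          z = runif(100, 5, 15)))
  pc <- point_cloud(c(g$x, trees$x), c(g$y, trees$y), c(rep(0, nrow(g)), trees$z))
  out <- classify_ground(pc, grid_size = 1, band = 0.2)
  expect_identical(out$ground, c(rep(TRUE, nrow(g)), rep(FALSE, 100)))
})

test_that("a single point is classified as ground", {
  out <- classify_ground(point_cloud(1, 1, 5))
  expect_true(out$ground)
})

test_that("DTM reproduces a plane through the ground points exactly", {
  g <- expand.grid(x = seq(0, 20, 1), y = seq(0, 20, 1))
  pc <- point_cloud(g$x, g$y, 0.1 * g$x + 0.05 * g$y,
                    ground = rep(TRUE, nrow(g)))
  dtm <- build_dtm(pc, resolution = 0.5)
  cc <- canopycce:::grid_centers(dtm)
  inhull <- cc$x > 0 & cc$x < 20
  expected <- outer(0.05 * cc$y, 0.1 * cc$x, "+")
  inside <- which(outer(cc$y > 0 & cc$y < 20, inhull, "&"))
  expect_lt(max(abs(dtm$values[inside] - expected[inside])), 1e-9)
})

test_that("DTM of a horizontal plane is constant and resolution scales cells", {
  withr::with_seed(2, {
    pc <- point_cloud(runif(100, 0, 10), runif(100, 0, 10), rep(3.5, 100),
                      ground = rep(TRUE, 100))
  })
  d1 <- build_dtm(pc, 1)
  expect_true(all(abs(d1$values - 3.5) < 1e-12))
  d2 <- build_dtm(pc, 0.5)
  expect_equal(d2$n_rows * d2$n_cols, 4 * d1$n_rows * d1$n_cols)
  expect_true(all(abs(d2$values - 3.5) < 1e-12))
})

test_that("DTM requires three non-degenerate ground points", {
  pc <- point_cloud(1:2, 1:2, 1:2, ground = c(TRUE, TRUE))
  expect_error(build_dtm(pc, 1), "terrain error")
  pc2 <- point_cloud(1:5, 1:5, c(0, 10, 11, 12, 13),
                     ground = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(build_dtm(pc2, 1), "terrain error")
})

test_that("height normalization subtracts the terrain and clamps at zero", {
  g <- expand.grid(x = 0:10, y = 0:10)
  ground <- point_cloud(g$x, g$y, rep(5, nrow(g)), ground = rep(TRUE, nrow(g)))
  dtm <- build_dtm(ground, 1)
  norm <- normalize_heights(ground, dtm)
  expect_true(all(abs(norm$z) < 1e-9))

  apex <- point_cloud(5, 5, 20)
  expect_equal(normalize_heights(apex, dtm)$z, 15, tolerance = 1e-9)

  below <- point_cloud(5, 5, 3)   # interpolation noise below terrain
  expect_equal(normalize_heights(below, dtm)$z, 0)
})

test_that("normalization is idempotent once heights are terrain-relative", {
  withr::with_seed(3, {
    sim <- generate_forest(forest_spec(plot_size = c(12, 12),
                                       stem_density = 0.03,
                                       point_density = 60, seed = 3))
  })
  cloud <- classify_ground(sim$cloud)
  dtm <- build_dtm(cloud, 0.5)
  n1 <- normalize_heights(cloud, dtm)
  zero_dtm <- dtm
  zero_dtm$values[] <- 0
  n2 <- normalize_heights(n1, zero_dtm)
  expect_equal(n2$z, n1$z)
})

test_that("normalized slope plot recovers the tallest tree height", {
  sim <- generate_forest(forest_spec(plot_size = c(15, 15), stem_density = 0.03,
                                     point_density = 80, slope_deg = 8,
                                     seed = 7))
  cloud <- classify_ground(sim$cloud)
  dtm <- build_dtm(cloud, 0.2)
  norm <- normalize_heights(cloud, dtm)
  expect_lt(abs(max(norm$z) - max(sim$truth$height)), 0.25)
})

test_that("pit-free CHM recovers a single cone apex and dominates naive CHM", {
  spec <- forest_spec(plot_size = c(8, 8), stem_density = 1 / 64,
                      height_range = c(18, 18), point_density = 250, seed = 9,
                      slope_deg = 0)
  sim <- generate_forest(spec)
  norm <- sim$cloud
  norm$z <- norm$z - canopycce:::terrain_z(spec, norm$x, norm$y)
  norm$z[norm$z < 0] <- 0
  chm <- pitfree_chm(norm, 0.1)
  expect_equal(max(chm$values), 18, tolerance = 1e-9)  # apex survives exactly

  # inject pits by random dropout inside the crown, then compare cell-wise
  withr::with_seed(10, keep <- runif(nrow(norm)) > 0.3)
  thin <- norm[keep | norm$ground, , drop = FALSE]
  pf <- pitfree_chm(thin, 0.1)
  nv <- naive_chm(thin, 0.1)
  expect_true(all(pf$values >= nv$values - 1e-9))
})

test_that("with all points below 2 m only the base layer contributes", {
  withr::with_seed(4, {
    pc <- point_cloud(runif(300, 0, 5), runif(300, 0, 5), runif(300, 0, 1.8))
  })
  pf <- pitfree_chm(pc, 0.5)
  nv <- naive_chm(pc, 0.5)
  # same triangulated surface; pit-free adds nothing above the base layer
  expect_true(all(pf$values >= nv$values - 1e-9))
  expect_equal(max(pf$values), max(nv$values), tolerance = 1e-9)
})

test_that("empty canopy raises the empty-CHM error", {
  pc <- point_cloud(1:3, 1:3, c(5, 6, 7), ground = rep(TRUE, 3))
  expect_error(pitfree_chm(pc, 0.5), "empty-CHM")
})
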