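test_that("projection stats capture extents and the highest point", {
  single <- data.frame(x = 2, y = 3, z = 10)
  ps <- projection_stats(single)
  expect_equal(c(ps$crown_x, ps$crown_y), c(0, 0))
  expect_equal(ps$x_max_z, 2)

  square <- data.frame(x = c(0, 1, 0, 1, 0.5), y = c(0, 0, 1, 1, 0.5),
                       z = c(1, 1, 1, 1, 5))
  ps2 <- projection_stats(square)
  expect_equal(c(ps2$crown_x, ps2$crown_y), c(1, 1))
  expect_equal(c(ps2$x_max_z, ps2$y_max_z), c(0.5, 0.5))

  sim <- generate_forest(forest_spec(plot_size = c(8, 8), stem_density = 1 / 64,
                                     crown_radius_range = c(2, 2),
                                     point_density = 300, seed = 51))
  crown <- sim$cloud[!sim$cloud$ground, , drop = FALSE]
  ps3 <- projection_stats(crown)
  expect_lt(abs(ps3$crown_x - 4), 0.4)
  expect_lt(abs(ps3$crown_y - 4), 0.4)
})

test_that("shape constraints accept centered symmetric crowns only", {
  mk <- function(cx, cy, xm, xz, ym = 0, yM = NULL, yz = NULL) {
    if (is.null(yM)) yM <- ym + cy
    if (is.null(yz)) yz <- (ym + yM) / 2
    list(crown_x = cx, crown_y = cy, x_min = xm, x_max = xm + cx,
         y_min = ym, y_max = yM, x_max_z = xz, y_max_z = yz)
  }
  expect_true(shape_ok(mk(4, 4, 0, 2)))          # symmetric, apex centered
  expect_false(shape_ok(mk(3, 1, 0, 1.5)))       # 3:1 ratio excluded exactly
  expect_false(shape_ok(mk(0, 4, 0, 0)))         # degenerate width

  # x-z test with Xmin = 0, Xmax = 8: bounds are (1, 7)
  expect_false(shape_ok(mk(8, 8, 0, 0.5, 0, 8, 4)))
  expect_true(shape_ok(mk(8, 8, 0, 4, 0, 8, 4)))
  expect_false(shape_ok(mk(8, 8, 0, 1, 0, 8, 4)))   # boundary excluded
  expect_false(shape_ok(mk(8, 8, 0, 7, 0, 8, 4)))
})

test_that("the 1/8 edge bounds equal the published closed form", {
  withr::with_seed(52, {
    for (rep in 1:1000) {
      xmin <- runif(1, -50, 50)
      xmax <- xmin + runif(1, 0.1, 30)
      lo <- xmin + (1 / 8) * (xmax - xmin)
      hi <- xmax - (1 / 8) * (xmax - xmin)
      expect_lt(abs(lo - (7 * xmin + xmax) / 8), 1e-12)
      expect_lt(abs(hi - (7 * xmax + xmin) / 8), 1e-12)
    }
  })
})

test_that("the width test rejects exactly the crowns with ratio >= 3", {
  withr::with_seed(53, {
    for (rep in 1:500) {
      cx <- runif(1, 0.1, 12)
      cy <- runif(1, 0.1, 12)
      ps <- list(crown_x = cx, crown_y = cy, x_min = 0, x_max = cx,
                 y_min = 0, y_max = cy, x_max_z = cx / 2, y_max_z = cy / 2)
      expect_equal(shape_ok(ps), max(cx, cy) / min(cx, cy) < 3)
    }
  })
})

test_that("shape test is invariant to translation and axis swap", {
  withr::with_seed(54, {
    for (rep in 1:20) {
      pts <- data.frame(x = runif(40, 0, 4), y = runif(40, 0, 4),
                        z = runif(40, 0, 10))
      base <- shape_ok(projection_stats(pts))
      shift <- pts
      shift$x <- shift$x + 123.4
      shift$y <- shift$y - 99.9
      expect_equal(shape_ok(projection_stats(shift)), base)
      swap <- data.frame(x = pts$y, y = pts$x, z = pts$z)
      expect_equal(shape_ok(projection_stats(swap)), base)
    }
  })
})

test_that("lowering the edge fraction never loses candidates", {
  withr::with_seed(55, {
    stats <- lapply(1:200, function(i)
      projection_stats(data.frame(x = runif(30, 0, 4), y = runif(30, 0, 4),
                                  z = runif(30, 0, 10))))
  })
  counts <- vapply(c(1 / 4, 1 / 8, 1 / 16), function(f)
    sum(vapply(stats, shape_ok, logical(1), edge_fraction = f)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("scale selection follows majority vote, Ncut tie-break, fallback", {
  # two clean cone crowns 6 m apart as the original points
  withr::with_seed(56, {
    mk_crown <- function(cx) {
      u <- runif(150)^(1 / 3)
      th <- runif(150, 0, 2 * pi)
      rad <- 1.5 * u * sqrt(runif(150))
      data.frame(x = cx + rad * cos(th), y = rad * sin(th), z = 15 - 9 * u)
    }
    pts <- rbind(mk_crown(0), mk_crown(6))
  })
  blob <- rep(1:2, each = 150)
  sp <- meanshift_voxelize(pts, bandwidth = 0.4)
  results <- cce_sweep(sp, cce_config(sigma = 30))
  sel <- select_scale(results, sp, pts)
  expect_equal(sel$m, 2)
  point_cluster <- sel$assignment[sp$member_map]
  purity <- max(table(point_cluster, blob)) / 150
  expect_gte(purity, 0.95)

  # majority rule on synthetic result lists: m = 2 backed by more scales
  fake <- function(k, m, ncut, assign) {
    structure(list(k = k, centers = unique(assign), assignment = assign,
                   m = m, ncut = ncut), class = "ClusterResult")
  }
  n <- nrow(sp$centers)
  left <- which(sp$centers$x < 3)
  a2 <- rep(max(left), n); a2[left] <- min(left)
  a1 <- rep(which.max(sp$centers$z), n)
  res_fake <- list(fake(2, 2L, 0.5, a2), fake(4, 2L, 0.1, a2),
                   fake(8, 2L, 0.9, a2), fake(16, 1L, 0, a1))
  pick <- select_scale(res_fake, sp, pts)
  expect_equal(pick$m, 2)
  expect_equal(pick$ncut, 0.1)            # lowest Ncut within winning group

  # no candidate at all -> NULL (caller keeps the watershed segment)
  bad <- rep(which.min(sp$centers$x), n)  # one cluster, apex at the edge
  flat <- list(fake(1, 1L, 0, bad))
  sel2 <- select_scale(flat, sp, data.frame(x = pts$x, y = pts$y,
                                            z = -pts$x))
  expect_null(sel2)
})
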