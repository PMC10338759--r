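# brute-force matching oracle: maximize pair count, then minimize total
# height difference, then total distance, over all one-to-one assignments
oracle_match <- function(detected, reference, params) {
  nd <- nrow(detected); nr <- nrow(reference)
  allowed <- function(i, j) {
    d <- sqrt((detected$x[i] - reference$x[j])^2 +
                (detected$y[i] - reference$y[j])^2)
    dh <- abs(detected$height[i] - reference$height[j])
    d <= params$max_xy_dist & dh / reference$height[j] <= params$max_rel_height_diff
  }
  best <- list(n = -1, dh = Inf, dist = Inf)
  recurse <- function(i, used, n, dh, dist) {
    if (i > nd) {
      if (n > best$n || (n == best$n && (dh < best$dh ||
          (dh == best$dh && dist < best$dist))))
        best <<- list(n = n, dh = dh, dist = dist)
      return(invisible())
    }
    recurse(i + 1, used, n, dh, dist)          # leave detected i unmatched
    for (j in seq_len(nr)) {
      if (used[j] || !allowed(i, j)) next
      used[j] <- TRUE
      d <- sqrt((detected$x[i] - reference$x[j])^2 +
                  (detected$y[i] - reference$y[j])^2)
      recurse(i + 1, used, n + 1,
              dh + abs(detected$height[i] - reference$height[j]), dist + d)
      used[j] <- FALSE
    }
  }
  recurse(1, rep(FALSE, nr), 0, 0, 0)
  best
}

test_that("perfect detection and empty detection give the boundary counts", {
  withr::with_seed(71, {
    ref <- tree_table(1:8, runif(8, 0, 40), runif(8, 0, 40), runif(8, 10, 25))
  })
  m <- match_trees(ref, ref)
  expect_equal(c(m$TP, m$FP, m$FN), c(8, 0, 0))
  none <- match_trees(tree_table(), ref)
  expect_equal(c(none$TP, none$FP, none$FN), c(0, 0, 8))
  expect_error(match_trees(ref, tree_table()), "empty reference")
})

test_that("greedy matching agrees with the exhaustive one-to-one oracle", {
  withr::with_seed(72, {
    for (rep in 1:15) {
      nr <- sample(2:6, 1); nd <- sample(1:6, 1)
      ref <- tree_table(seq_len(nr), runif(nr, 0, 25), runif(nr, 0, 25),
                        runif(nr, 10, 25))
      src <- sample(nr, nd, replace = TRUE)
      det <- tree_table(seq_len(nd),
                        ref$x[src] + rnorm(nd, 0, 1.5),
                        ref$y[src] + rnorm(nd, 0, 1.5),
                        pmax(1, ref$height[src] + rnorm(nd, 0, 1.2)))
      p <- match_params()
      got <- match_trees(det, ref, p)
      want <- oracle_match(det, ref, p)
      expect_equal(got$TP, want$n)
    }
  })
})

test_that("detection metrics match hand evaluation and published identities", {
  m <- compute_detection_metrics(3, 1, 1)
  expect_equal(m$R_match, 0.75)
  expect_equal(m$R_extraction, 1.00)
  expect_equal(m$R_commission, 0.25)
  expect_equal(m$R_omission, 0.25)
  expect_equal(m$F, 0.75)
  # identities hold for arbitrary integer counts
  withr::with_seed(73, {
    for (rep in 1:50) {
      TP <- sample(0:50, 1); FP <- sample(0:20, 1); FN <- sample(0:30, 1)
      if (TP + FN == 0) FN <- 1
      mm <- suppressWarnings(compute_detection_metrics(TP, FP, FN))
      expect_equal(mm$R_omission, 1 - mm$R_match)
      if (TP + FP > 0)
        expect_equal(mm$R_commission, 1 - mm$R_match / mm$R_extraction)
    }
  })
  expect_equal(compute_detection_metrics(0, 3, 5)$F, 0)
  expect_warning(compute_detection_metrics(0, 0, 5), "commission")
})

test_that("rate-derived metrics reproduce the two-decimal published cells", {
  p1 <- metrics_from_rates(0.61, 0.80)
  expect_equal(round(p1$F, 2), 0.68)
  expect_equal(round(p1$R_omission, 2), 0.39)
  p4 <- metrics_from_rates(0.71, 0.92)
  expect_equal(round(p4$R_commission, 2), 0.23)
})

test_that("metrics are invariant to input row order", {
  withr::with_seed(74, {
    ref <- tree_table(1:6, runif(6, 0, 30), runif(6, 0, 30), runif(6, 12, 22))
    det <- tree_table(1:5, ref$x[1:5] + rnorm(5, 0, 1),
                      ref$y[1:5] + rnorm(5, 0, 1),
                      ref$height[1:5] + rnorm(5, 0, 0.8))
    perm_d <- sample(5); perm_r <- sample(6)
  })
  a <- match_trees(det, ref)
  b <- match_trees(det[perm_d, ], ref[perm_r, ])
  expect_equal(c(a$TP, a$FP, a$FN), c(b$TP, b$FP, b$FN))
})

test_that("height accuracy matches hand-computed R2 and RMSE", {
  perf <- height_accuracy(c(10, 15, 20), c(10, 15, 20))
  expect_equal(perf$r2, 1)
  expect_equal(perf$rmse, 0)
  off <- height_accuracy(c(12, 17, 22), c(10, 15, 20))
  expect_equal(off$rmse, 2)
  hand <- height_accuracy(c(11, 14, 21), c(10, 15, 20))
  expect_equal(hand$rmse, 1)
  expect_equal(hand$r2, 1 - 3 / 50)
  expect_error(height_accuracy(c(1, 2), c(5, 5)), "variance")
  expect_error(height_accuracy(1, 1), "2 matched pairs")
})
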