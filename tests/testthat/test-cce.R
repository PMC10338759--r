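test_that("weighted distance matrix matches hand-evaluated cases", {
  sp <- list(centers = data.frame(x = c(0, 3), y = c(0, 4), z = c(0, 0)),
             weights = c(1L, 2L))
  D <- build_distance_matrix(sp, vr = 0.5)
  expect_equal(D[1, 2], 10)                 # 1 * 2 * sqrt(9 + 16)
  expect_equal(D[2, 1], 10)
  expect_equal(diag(D), c(0, 0))

  vert <- list(centers = data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 6)),
               weights = c(1L, 1L))
  expect_equal(build_distance_matrix(vert, vr = 1 / 6)[1, 2], sqrt(6))

  same <- list(centers = data.frame(x = c(1, 1), y = c(2, 2), z = c(3, 3)),
               weights = c(5L, 7L))
  expect_equal(build_distance_matrix(same, vr = 1)[1, 2], 0)

  # weight_mode = "none" drops the n_i * n_j factor
  expect_equal(build_distance_matrix(sp, vr = 0.5, weight_mode = "none")[1, 2], 5)
})

test_that("Gaussian similarity is a strictly decreasing kernel of distance", {
  D <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(gaussian_similarity(D, sigma = 2)[1, 2], exp(-1))
  expect_equal(diag(gaussian_similarity(D, 5)), c(1, 1))
  expect_error(gaussian_similarity(D, 0), "sigma")
  d <- seq(0, 10, 0.5)
  s <- exp(-d^2 / 9)
  expect_true(all(diff(s) < 0))
})

test_that("degree normalization matches the two-point hand case", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  N <- normalize_similarity(S)
  expect_equal(N$S, matrix(c(2, 1, 1, 2) / 3, 2))
  expect_equal(N$degrees, c(1.5, 1.5))
  expect_equal(normalize_similarity(diag(2))$S, diag(2))
  # any 2-point system has equal degrees, so rows sum to 1
  for (s in c(0.1, 0.4, 0.9)) {
    Ns <- normalize_similarity(matrix(c(1, s, s, 1), 2))$S
    expect_equal(rowSums(Ns), c(1, 1))
  }
})

test_that("matrix powers match naive multiplication and the eigen limit", {
  S <- matrix(c(2, 1, 1, 2) / 3, 2)
  expect_equal(connectivity_power(S, 1), S)
  expect_equal(connectivity_power(S, 2), matrix(c(5, 4, 4, 5) / 9, 2))
  # naive repeated multiplication oracle, k <= 8, n <= 20
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- sample(3:20, 1)
      M <- normalize_similarity(random_similarity(n))$S
      naive <- diag(n)
      for (k in 1:8) {
        naive <- naive %*% M
        expect_lt(max(abs(connectivity_power(M, k) - naive)), 1e-10)
      }
    }
  })
  # k -> infinity: eigenvalues 1 and 1/3, so entries approach 1/2 exactly
  expect_equal(connectivity_power(S, 2^30), matrix(0.5, 2, 2),
               tolerance = 1e-6)   # 30 squarings accumulate rounding drift
})

test_that("center rule and assignment match exhaustive brute force", {
  S <- matrix(c(2, 1, 1, 2) / 3, 2)
  expect_equal(find_centers(connectivity_power(S, 2)), c(1L, 2L))
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(3:15, 1)
      M <- normalize_similarity(random_similarity(n))$S
      S_k <- connectivity_power(M, sample(1:8, 1))
      centers <- find_centers(S_k)
      expect_equal(centers, oracle_centers(S_k))
      if (length(centers)) {
        res <- assign_points(S_k, centers)
        expect_equal(res$assignment, oracle_assign(S_k, centers))
        expect_equal(res$m, length(centers))
        expect_equal(res$assignment[centers], centers)
      }
    }
  })
})

test_that("at k = 1 well-separated distinct points are all centers", {
  withr::with_seed(43, {
    p <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100), z = 0)
  })
  sp <- list(centers = p, weights = rep(1L, 12))
  S <- normalize_similarity(gaussian_similarity(
    build_distance_matrix(sp, 1), sigma = 5))$S
  expect_equal(find_centers(S), 1:12)
})

test_that("normalized cut matches hand values and vanishes for one cluster", {
  S <- matrix(c(2, 1, 1, 2) / 3, 2)
  expect_equal(normalized_cut(S, c(1, 1)), 0)
  expect_equal(normalized_cut(S, c(1, 2)), 2 / 3)
  B <- diag(4)
  B[1, 2] <- B[2, 1] <- B[3, 4] <- B[4, 3] <- 0.5
  expect_equal(normalized_cut(B, c(1, 1, 2, 2)), 0)  # block-diagonal split
})

test_that("matrices stay symmetric through the whole chain", {
  withr::with_seed(44, {
    p <- data.frame(x = runif(25, 0, 10), y = runif(25, 0, 10),
                    z = runif(25, 0, 15))
    sp <- list(centers = p, weights = sample(1:20, 25, replace = TRUE))
  })
  D <- build_distance_matrix(sp, 1 / 6)
  expect_lt(max(abs(D - t(D))), 1e-12)
  St <- gaussian_similarity(D, 30)
  expect_lt(max(abs(St - t(St))), 1e-12)
  S <- normalize_similarity(St)$S
  expect_lt(max(abs(S - t(S))), 1e-12)
  for (k in c(2, 4, 16)) {
    Sk <- connectivity_power(S, k)
    expect_lt(max(abs(Sk - t(Sk))), 1e-12)
  }
})

test_that("large k yields a single center at the Perron eigenvector argmax", {
  withr::with_seed(45, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      p <- data.frame(x = runif(n, 0, 8), y = runif(n, 0, 8),
                      z = runif(n, 0, 4))
      sp <- list(centers = p, weights = rep(1L, n))
      S <- normalize_similarity(gaussian_similarity(
        build_distance_matrix(sp, 1 / 6), sigma = 6))$S
      S_k <- S
      for (i in 1:45) {                 # k = 2^45 with renormalization
        S_k <- S_k %*% S_k
        S_k <- (S_k + t(S_k)) / 2
        S_k <- S_k / max(S_k)
      }
      centers <- find_centers(S_k)
      ev <- eigen(S, symmetric = TRUE)$vectors[, 1]
      expect_equal(centers, which.max(abs(ev)))
    }
  })
})

test_that("the scale sweep separates two distant blobs then merges them", {
  one <- list(centers = data.frame(x = 0, y = 0, z = 10), weights = 5L,
              member_map = 1L)
  res <- cce_sweep(one, cce_config())
  expect_equal(length(res), 1)
  expect_equal(res[[1]]$m, 1)
  expect_equal(res[[1]]$k, 1)

  two <- list(centers = data.frame(x = c(0, 9), y = c(0, 0), z = c(5, 5)),
              weights = c(1L, 1L), member_map = 1:2)
  res2 <- cce_sweep(two, cce_config(sigma = 3))   # d = 3 sigma: weak link
  ms <- vapply(res2, `[[`, integer(1), "m")
  expect_equal(ms[1], 2)                   # micro scale: separate
  expect_equal(ms[length(ms)], 1)          # macro scale: merged

  sp <- two_blob_superpoints()
  res3 <- cce_sweep(sp, cce_config(sigma = 5))
  m2 <- Filter(function(r) r$m == 2, res3)
  expect_gt(length(m2), 0)
  blob <- rep(1:2, each = 30)
  pure <- vapply(m2, function(r) {
    cl <- r$assignment
    all(vapply(split(blob, cl), function(g) length(unique(g)) == 1, logical(1)))
  }, logical(1))
  expect_true(any(pure))
})
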