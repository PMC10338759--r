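#' Connection-center-evolution clustering
#'
#' The CCE operations cluster one segment's super-points by powers of a
#' normalized Gaussian similarity matrix. A weighted pairwise distance is
#' converted to similarities by a Gaussian kernel, symmetrically normalized
#' by the degree matrix, and raised to increasing powers k; points whose
#' k-order self-connectivity (diagonal entry) dominates their row become
#' cluster centers, all other points are assigned to the center with the
#' highest relative connectivity to them. At k = 1 every point is its own
#' center; as k grows, centers merge until a single one remains.
#'
#' @name cce
NULL

#' CCE configuration
#'
#' @param vr vertical distance correction factor in (0, 1] (default 1/6),
#'   down-weighting height differences to compensate occlusion-thinned lower
#'   crowns.
#' @param sigma Gaussian kernel scale in the units of the weighted distance
#'   (default 30).
#' @param max_power largest connectivity order in the sweep; the schedule is
#'   the powers of two `1, 2, 4, ..., max_power` (default `2^20`).
#' @param weight_mode `"printed"` multiplies the distance by the product of
#'   voxel weights; `"none"` ignores weights (sensitivity switch).
#' @return configuration list.
#' @export
cce_config <- function(vr = 1 / 6, sigma = 30, max_power = 2^20,
                       weight_mode = c("printed", "none")) {
  stopifnot(vr > 0, vr <= 1, sigma > 0, max_power >= 1)
  list(vr = vr, sigma = sigma, max_power = max_power,
       weight_mode = match.arg(weight_mode))
}

#' Weighted pairwise distance matrix
#'
#' `d[i, j] = n_i * n_j * sqrt(dx^2 + dy^2 + vr * dz^2)` between super-points
#' i and j with weights `n_i`, `n_j`; zero diagonal, symmetric.
#'
#' @param sp a `SuperPointSet` from [meanshift_voxelize()], or any list with
#'   `centers` (x, y, z) and `weights`.
#' @param vr vertical distance correction factor.
#' @param weight_mode see [cce_config()].
#' @return n x n distance matrix.
#' @export
build_distance_matrix <- function(sp, vr = 1 / 6,
                                  weight_mode = c("printed", "none")) {
  weight_mode <- match.arg(weight_mode)
  cx <- sp$centers$x; cy <- sp$centers$y; cz <- sp$centers$z
  dx <- outer(cx, cx, "-"); dy <- outer(cy, cy, "-"); dz <- outer(cz, cz, "-")
  d <- sqrt(dx^2 + dy^2 + vr * dz^2)
  if (weight_mode == "printed") {
    w <- as.numeric(sp$weights)
    d <- d * outer(w, w)
  }
  diag(d) <- 0
  d
}

#' Gaussian similarity from distances
#'
#' `s[i, j] = exp(-d[i, j]^2 / sigma^2)`: unit diagonal, entries in (0, 1].
#'
#' @param D distance matrix.
#' @param sigma Gaussian kernel scale (> 0).
#' @return similarity matrix.
#' @export
gaussian_similarity <- function(D, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-(D^2) / sigma^2)
}

#' Symmetric degree normalization of a similarity matrix
#'
#' `S = Dtilde^(-1/2) Stilde Dtilde^(-1/2)` with degrees
#' `d_i = sum_j s[i, j]`.
#'
#' @param S_tilde similarity matrix with positive degrees.
#' @return list with the normalized matrix `S` and the `degrees` vector.
#' @export
normalize_similarity <- function(S_tilde) {
  deg <- rowSums(S_tilde)
  if (any(deg <= 0)) stop("zero degree in similarity matrix")
  inv <- 1 / sqrt(deg)
  S <- S_tilde * outer(inv, inv)
  list(S = S, degrees = deg)
}

#' k-th power of the normalized similarity matrix
#'
#' Computed by repeated squaring. Exposed mainly for testing; the sweep in
#' [cce_sweep()] squares incrementally along its schedule.
#'
#' @param S normalized similarity matrix.
#' @param k integer order >= 1.
#' @return `S^k`.
#' @export
connectivity_power <- function(S, k) {
  stopifnot(k >= 1, k == round(k))
  out <- NULL
  base <- S
  k <- as.integer(k)
  while (k > 0L) {
    if (bitwAnd(k, 1L)) out <- if (is.null(out)) base else out %*% base
    k <- bitwShiftR(k, 1L)
    if (k > 0L) base <- base %*% base
  }
  (out + t(out)) / 2
}

#' k-order cluster centers
#'
#' Centers are the indices whose diagonal entry strictly exceeds every
#' off-diagonal entry of their row. Exact ties are resolved by declaring
#' the lower index a center.
#'
#' @param S_k k-th power of the normalized similarity matrix.
#' @return integer vector of center indices (possibly empty).
#' @export
find_centers <- function(S_k) {
  n <- nrow(S_k)
  if (n == 1L) return(1L)
  centers <- integer(0)
  for (i in seq_len(n)) {
    row <- S_k[i, -i]
    di <- S_k[i, i]
    if (di > max(row)) centers <- c(centers, i)
    else if (di == max(row)) {
      # tie: lower index wins center status
      ties <- setdiff(which(S_k[i, ] == di), i)
      if (all(ties > i)) centers <- c(centers, i)
    }
  }
  centers
}

#' Assign points to centers by relative connectivity
#'
#' Point j is assigned to the center c maximizing
#' `rcon_k(c, j) = S_k[c, j] / S_k[c, c]`; ties go to the lowest center
#' index.
#'
#' @param S_k k-th power of the normalized similarity matrix.
#' @param centers integer center indices (non-empty).
#' @param k the order, recorded in the result.
#' @return A `ClusterResult`: list with `k`, `centers`, `assignment`
#'   (center index per point, values in `centers`), `m` (cluster count) and
#'   `ncut` (filled by [cce_sweep()]; `NA` here).
#' @export
assign_points <- function(S_k, centers, k = NA_integer_) {
  if (!length(centers)) stop("centers must be non-empty")
  rcon <- S_k[centers, , drop = FALSE] / diag(S_k)[centers]
  best <- apply(rcon, 2, which.max)     # first (= lowest center) on ties
  assignment <- centers[best]
  assignment[centers] <- centers        # centers always belong to themselves
  structure(list(k = k, centers = centers, assignment = assignment,
                 m = length(centers), ncut = NA_real_),
            class = "ClusterResult")
}

#' Normalized cut of a partition under S_k
#'
#' `Ncut = sum_l cut(P_l, not P_l) / Vol(P_l)` with cut and volume computed
#' from the k-order connectivities. Lower is better; a single cluster has
#' Ncut 0.
#'
#' @param S_k k-th power of the normalized similarity matrix.
#' @param assignment cluster id per point (e.g. center indices).
#' @return the Ncut value.
#' @export
normalized_cut <- function(S_k, assignment) {
  parts <- unique(assignment)
  total <- 0
  for (p in parts) {
    inp <- assignment == p
    if (!any(inp)) stop("empty part in partition")
    vol <- sum(S_k[inp, , drop = FALSE])
    cut <- sum(S_k[inp, !inp, drop = FALSE])
    total <- total + cut / vol
  }
  total
}

#' Sweep connectivity orders and cluster at each scale
#'
#' Builds the similarity state from the super-points, then walks the
#' power-of-two schedule `k = 1, 2, 4, ..., max_power` by successive
#' squaring, extracting centers, assignment and Ncut at each k. After each
#' squaring the matrix is rescaled by its maximum entry (the center and
#' assignment rules are invariant to positive scaling) to avoid floating
#' underflow. Scales with an empty center set are omitted; the sweep stops
#' early once a single cluster persists for two consecutive scales.
#'
#' @param sp a `SuperPointSet`.
#' @param config a [cce_config()].
#' @return list of `ClusterResult`, one per retained scale.
#' @export
cce_sweep <- function(sp, config = cce_config()) {
  n <- nrow(sp$centers)
  if (n == 0L) stop("empty super-point set")
  if (n == 1L) {
    res <- structure(list(k = 1, centers = 1L, assignment = 1L, m = 1L,
                          ncut = 0), class = "ClusterResult")
    return(list(res))
  }
  D <- build_distance_matrix(sp, config$vr, config$weight_mode)
  S <- normalize_similarity(gaussian_similarity(D, config$sigma))$S
  results <- list()
  S_k <- S
  k <- 1
  ones_run <- 0L
  repeat {
    centers <- find_centers(S_k)
    if (length(centers)) {
      res <- assign_points(S_k, centers, k = k)
      res$ncut <- normalized_cut(S_k, res$assignment)
      results[[length(results) + 1L]] <- res
      ones_run <- if (res$m == 1L) ones_run + 1L else 0L
      if (ones_run >= 2L) break
    }
    if (k >= config$max_power) break
    S_k <- S_k %*% S_k
    S_k <- (S_k + t(S_k)) / 2
    mx <- max(S_k)
    if (mx <= 0 || !is.finite(mx)) break
    S_k <- S_k / mx
    k <- k * 2
  }
  results
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k = %g, m = %d clusters, Ncut = %.4g\n",
              x$k, x$m, x$ncut))
  invisible(x)
}
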