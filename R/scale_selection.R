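#' Tri-planar projection statistics of a cluster
#'
#' Crown extents and highest-point coordinates of a cluster's member points,
#' projected to the X-Y, X-Z and Y-Z planes: `CrownX = Xmax - Xmin`,
#' `CrownY = Ymax - Ymin`, and `XmaxZ` / `YmaxZ` the x / y coordinate of the
#' highest member point (first on exact height ties).
#'
#' @param points data frame with `x`, `y`, `z` of the cluster's member
#'   points (original points, not super-points).
#' @return list with `crown_x`, `crown_y`, `x_min`, `x_max`, `y_min`,
#'   `y_max`, `x_max_z`, `y_max_z`.
#' @export
projection_stats <- function(points) {
  if (nrow(points) == 0L) stop("empty cluster")
  top <- which.max(points$z)
  list(crown_x = max(points$x) - min(points$x),
       crown_y = max(points$y) - min(points$y),
       x_min = min(points$x), x_max = max(points$x),
       y_min = min(points$y), y_max = max(points$y),
       x_max_z = points$x[top], y_max_z = points$y[top])
}

#' Crown shape constraints
#'
#' A cluster passes when all three projection tests hold strictly:
#' the crown widths differ by less than their mean (equivalently, the wider
#' crown is less than 3x the narrower), and the highest point lies farther
#' than `edge_fraction` of the crown width from either crown edge, in both
#' the X-Z and Y-Z projections. With `edge_fraction = 1/8` the bounds reduce
#' to `(7*Xmin + Xmax)/8 < XmaxZ < (7*Xmax + Xmin)/8` (and the analogous Y
#' form). A zero crown width in either axis fails.
#'
#' @param ps projection stats from [projection_stats()].
#' @param edge_fraction top-to-edge minimum distance as a fraction of the
#'   crown width (default 1/8).
#' @return logical.
#' @export
shape_ok <- function(ps, edge_fraction = 1 / 8) {
  if (ps$crown_x <= 0 || ps$crown_y <= 0) return(FALSE)
  if (!(abs(ps$crown_x - ps$crown_y) < (ps$crown_x + ps$crown_y) / 2))
    return(FALSE)
  lo_x <- ps$x_min + edge_fraction * ps$crown_x
  hi_x <- ps$x_max - edge_fraction * ps$crown_x
  if (!(ps$x_max_z > lo_x && ps$x_max_z < hi_x)) return(FALSE)
  lo_y <- ps$y_min + edge_fraction * ps$crown_y
  hi_y <- ps$y_max - edge_fraction * ps$crown_y
  ps$y_max_z > lo_y && ps$y_max_z < hi_y
}

#' Select the optimal clustering scale for one segment
#'
#' A sweep result is a *candidate* when every one of its clusters passes
#' [shape_ok()] on the original member points. Candidates vote by their
#' cluster count m: the m backed by the most candidate scales wins (ties go
#' to the smaller m), and within the winning group the result with the
#' minimal Ncut is returned. If no scale yields a candidate, the segment is
#' kept whole as a single cluster (`NULL` is returned and the caller keeps
#' the watershed segment).
#'
#' @param results list of `ClusterResult` from [cce_sweep()].
#' @param sp the `SuperPointSet` the sweep ran on (for the member map).
#' @param points original points of the segment (same order as the member
#'   map).
#' @param edge_fraction see [shape_ok()].
#' @return the selected `ClusterResult`, or `NULL` when no candidate exists.
#' @export
select_scale <- function(results, sp, points, edge_fraction = 1 / 8) {
  if (!length(results)) return(NULL)
  candidate <- vapply(results, function(res) {
    point_cluster <- res$assignment[sp$member_map]
    for (c in unique(point_cluster)) {
      ps <- projection_stats(points[point_cluster == c, , drop = FALSE])
      if (!shape_ok(ps, edge_fraction)) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(candidate)) return(NULL)
  cand <- results[candidate]
  ms <- vapply(cand, `[[`, integer(1), "m")
  votes <- table(ms)
  best_m <- as.integer(names(votes)[votes == max(votes)])
  best_m <- min(best_m)                       # tie -> smaller m
  group <- cand[ms == best_m]
  ncuts <- vapply(group, `[[`, numeric(1), "ncut")
  group[[which.min(ncuts)]]
}
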