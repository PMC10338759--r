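#' Mean-shift voxelization of a point set
#'
#' Reduces a crown segment's points to weighted super-points by flat-kernel
#' mean shift in the anisotropic metric `(dx, dy, sqrt(vr)*dz)` — the same
#' vertical down-weighting used by the clustering distance — then merges
#' converged modes closer than half the bandwidth. Each super-point carries
#' the weighted centroid of its member points and its member count as
#' weight, so the voxel set conserves point mass exactly.
#'
#' @param points a [point_cloud()] (or data frame with x, y, z), usually one
#'   watershed segment.
#' @param bandwidth flat kernel radius in meters (> 0).
#' @param vr vertical distance correction factor in (0, 1] (default 1/6).
#' @param tol convergence tolerance for the mode shift (meters, default 1e-3).
#' @param max_iter maximum shift iterations per point (default 100).
#' @return A `SuperPointSet`: list with `centers` (data frame x, y, z),
#'   integer `weights`, and `member_map` (super-point index per input point).
#' @export
meanshift_voxelize <- function(points, bandwidth, vr = 1 / 6, tol = 1e-3,
                               max_iter = 100L) {
  if (nrow(points) == 0L) stop("empty point set")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be > 0")
  res <- cpp_meanshift_voxelize(points$x, points$y, points$z,
                                bandwidth, vr, tol, as.integer(max_iter))
  sp <- list(centers = data.frame(x = res$x, y = res$y, z = res$z),
             weights = res$weight, member_map = res$member,
             bandwidth = bandwidth, vr = vr)
  class(sp) <- "SuperPointSet"
  stopifnot(sum(sp$weights) == nrow(points))
  sp
}

#' @export
print.SuperPointSet <- function(x, ...) {
  cat(sprintf("SuperPointSet: %d super-points from %d points (%.1fx reduction)\n",
              nrow(x$centers), sum(x$weights),
              sum(x$weights) / nrow(x$centers)))
  invisible(x)
}

# default voxel bandwidth by local point density (pts/m^2), mirroring the
# CHM resolution convention: finer for dense ULS clouds
auto_bandwidth <- function(density) if (density >= 100) 0.3 else 0.6
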