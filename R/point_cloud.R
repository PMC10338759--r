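#' Point cloud container
#'
#' A `PointCloud` is a plain `data.frame` with class `"PointCloud"` holding
#' per-point coordinates in a projected metric CRS, plus optional per-point
#' attributes added by pipeline stages:
#'
#' * `x`, `y`, `z` — coordinates in meters (required, finite),
#' * `ground` — logical ground classification flag (optional),
#' * `tree_label` — non-negative integer tree id, 0 = unassigned (optional).
#'
#' @param x,y,z numeric coordinate vectors of equal length (meters).
#' @param ground optional logical vector of the same length.
#' @param tree_label optional non-negative integer vector of the same length.
#' @return A `PointCloud` data frame.
#' @examples
#' pc <- point_cloud(c(0, 1), c(0, 0), c(0, 10))
#' nrow(pc)
#' @export
point_cloud <- function(x, y, z, ground = NULL, tree_label = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (n < 1L) stop("point cloud must contain at least one point")
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("all coordinates must be finite")
  pc <- data.frame(x = x, y = y, z = z)
  if (!is.null(ground)) {
    stopifnot(length(ground) == n)
    pc$ground <- as.logical(ground)
  }
  if (!is.null(tree_label)) {
    stopifnot(length(tree_label) == n, all(tree_label >= 0))
    pc$tree_label <- as.integer(tree_label)
  }
  class(pc) <- c("PointCloud", "data.frame")
  pc
}

#' @export
print.PointCloud <- function(x, ...) {
  cat(sprintf("PointCloud: %d points\n", nrow(x)))
  cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  if (!is.null(x$ground))
    cat(sprintf("  ground points: %d\n", sum(x$ground)))
  if (!is.null(x$tree_label))
    cat(sprintf("  labeled trees: %d\n", length(setdiff(unique(x$tree_label), 0L))))
  invisible(x)
}

as_point_cloud <- function(df) {
  point_cloud(df$x, df$y, df$z, ground = df$ground,
              tree_label = df$tree_label)
}
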