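#' Classify ground points
#'
#' If the cloud already carries ground flags (e.g. from a pre-classified LAS
#' file or an external cloth-simulation filter) they are passed through
#' unchanged. Otherwise a simple minimum-grid classifier runs: the lowest
#' point of each `grid_size` cell defines a minimum surface (TIN
#' interpolated), and points within `band` meters above that surface are
#' flagged as ground.
#'
#' @param cloud a [point_cloud()].
#' @param grid_size minimum-grid cell size in meters (default 1).
#' @param band vertical tolerance above the minimum surface (default 0.2 m).
#' @return The cloud with a logical `ground` column.
#' @export
classify_ground <- function(cloud, grid_size = 1, band = 0.2) {
  if (nrow(cloud) == 0L) stop("empty point cloud")
  if (!is.null(cloud$ground)) return(cloud)
  if (nrow(cloud) == 1L) { cloud$ground <- TRUE; return(cloud) }
  gx <- floor(cloud$x / grid_size)
  gy <- floor(cloud$y / grid_size)
  dt <- data.table::data.table(gx = gx, gy = gy, x = cloud$x, y = cloud$y,
                               z = cloud$z)
  mins <- dt[, .SD[which.min(z)], by = .(gx, gy)]
  if (nrow(mins) < 3L) {
    cloud$ground <- cloud$z <= min(cloud$z) + band
  } else {
    surf <- cpp_tin_interp(mins$x, mins$y, mins$z, cloud$x, cloud$y,
                           TRUE, 0)
    cloud$ground <- cloud$z <= surf + band
  }
  if (all(cloud$ground))
    warning("minimum-grid classifier flagged every point as ground")
  if (!any(cloud$ground))
    warning("minimum-grid classifier flagged no point as ground")
  cloud
}

#' Build a digital terrain model by TIN interpolation
#'
#' Linearly interpolates the ground-classified points on a Delaunay
#' triangulation, sampled at cell centers of a regular grid covering the
#' cloud's xy extent. Cells outside the convex hull of the ground points are
#' filled with the nearest ground point's elevation.
#'
#' @param cloud a [point_cloud()] with ground flags (see [classify_ground()]).
#' @param resolution cell size in meters.
#' @return A [raster_grid()] DTM.
#' @export
build_dtm <- function(cloud, resolution) {
  if (is.null(cloud$ground)) stop("cloud has no ground classification; run classify_ground() first")
  g <- cloud[cloud$ground, , drop = FALSE]
  if (nrow(g) < 3L) stop("terrain error: need at least 3 ground points")
  # collapse duplicate xy locations (keep the lowest return)
  dt <- data.table::data.table(x = g$x, y = g$y, z = g$z)
  dt <- dt[, .(z = min(z)), by = .(x, y)]
  if (nrow(dt) < 3L) stop("terrain error: need at least 3 distinct ground locations")
  rng <- apply(cbind(dt$x, dt$y), 2, range)
  if (abs(det(cbind(dt$x[2:3] - dt$x[1], dt$y[2:3] - dt$y[1]))) < 1e-12 &&
      nrow(dt) == 3L)
    stop("terrain error: ground points are collinear")
  grid <- empty_grid_for(cloud, resolution)
  cc <- grid_centers(grid)
  q <- expand.grid(x = cc$x, y = cc$y)
  z <- cpp_tin_interp(dt$x, dt$y, dt$z, q$x, q$y, TRUE, 0)
  grid$values <- matrix(z, nrow = grid$n_rows, ncol = grid$n_cols,
                        byrow = TRUE)
  grid
}

# grid covering the cloud extent, origin snapped to a resolution multiple
empty_grid_for <- function(cloud, resolution) {
  ox <- floor(min(cloud$x) / resolution) * resolution
  oy <- floor(min(cloud$y) / resolution) * resolution
  nc <- max(1L, ceiling((max(cloud$x) - ox) / resolution + 1e-9))
  nr <- max(1L, ceiling((max(cloud$y) - oy) / resolution + 1e-9))
  if (max(cloud$x) >= ox + nc * resolution) nc <- nc + 1L
  if (max(cloud$y) >= oy + nr * resolution) nr <- nr + 1L
  raster_grid(matrix(NA_real_, nr, nc), ox, oy, resolution)
}

#' Normalize point heights against a DTM
#'
#' Replaces each point's elevation by its height above terrain,
#' `z - DTM(x, y)`, with the DTM sampled bilinearly at the point location.
#' Points outside the DTM extent use the nearest cell value (counted in a
#' warning). Negative heights (interpolation noise below terrain) are
#' clamped to 0.
#'
#' @param cloud a [point_cloud()].
#' @param dtm a [raster_grid()] covering the cloud's xy extent.
#' @return The cloud with normalized `z`.
#' @export
normalize_heights <- function(cloud, dtm) {
  terrain <- sample_bilinear(dtm, cloud$x, cloud$y)
  outside <- cloud$x < dtm$origin_x | cloud$y < dtm$origin_y |
    cloud$x >= dtm$origin_x + dtm$n_cols * dtm$cell_size |
    cloud$y >= dtm$origin_y + dtm$n_rows * dtm$cell_size
  if (any(outside))
    warning(sum(outside), " points outside DTM extent; nearest cell used")
  cloud$z <- pmax(cloud$z - terrain, 0)
  cloud
}

#' Pit-free canopy height model
#'
#' Generates the canopy height model from a height-normalized cloud by the
#' layered maximum method: for each layer threshold, a partial CHM is TIN
#' interpolated from the per-cell highest points at or above that
#' threshold, and the final CHM is the cell-wise maximum of all partial
#' CHMs together with each cell's own highest point — so the result always
#' dominates the naive highest-point raster and tree apices survive
#' exactly. Above the 2 m layer, triangles with any edge longer than
#' `edge_cutoff_factor` times the cell size are dropped so interpolation
#' does not bridge distinct crowns. Cells covered by no layer are 0.
#'
#' @param cloud a height-normalized [point_cloud()] (min z >= 0).
#' @param resolution cell size in meters.
#' @param layers increasing layer thresholds in meters, starting at 0
#'   (default `c(0, 2, 5, 10, 15)`).
#' @param edge_cutoff_factor TIN edge cutoff in multiples of the cell size
#'   for layers at or above 2 m (default 3; 0 disables).
#' @param grid optional template [raster_grid()] defining the output frame
#'   (values ignored); defaults to a grid covering the cloud.
#' @return A [raster_grid()] CHM.
#' @export
pitfree_chm <- function(cloud, resolution, layers = c(0, 2, 5, 10, 15),
                        edge_cutoff_factor = 3, grid = NULL) {
  if (min(cloud$z) < -1e-9) stop("cloud must be height-normalized (min z >= 0)")
  if (is.unsorted(layers, strictly = TRUE) || layers[1] != 0)
    stop("layer thresholds must be strictly increasing and start at 0")
  if (is.null(grid)) grid <- empty_grid_for(cloud, resolution)
  nonground <- if (!is.null(cloud$ground)) cloud[!cloud$ground, , drop = FALSE] else cloud
  if (nrow(nonground) == 0L || max(nonground$z) < layers[1])
    stop("empty-CHM error: no points at or above the first layer threshold")
  idx <- cell_index(grid, nonground$x, nonground$y, clamp = TRUE)
  dt <- data.table::data.table(cell = (idx$col - 1L) * grid$n_rows + idx$row,
                               x = nonground$x, y = nonground$y,
                               z = nonground$z)
  cc <- grid_centers(grid)
  q <- expand.grid(x = cc$x, y = cc$y)   # row-major over (y rows, x cols)
  chm <- matrix(-Inf, grid$n_rows, grid$n_cols)
  # each cell's own highest point competes in the maximum, so the result
  # dominates the naive highest-point raster (and keeps tree apices exact)
  top0 <- dt[, .(z = max(z)), by = cell]
  chm[top0$cell] <- top0$z
  for (t in layers) {
    lay <- dt[z >= t]
    if (nrow(lay) == 0L) next
    top <- lay[, .SD[which.max(z)], by = cell]
    if (nrow(top) < 3L) {
      # too few points to triangulate: paint their own cells only
      m <- matrix(-Inf, grid$n_rows, grid$n_cols)
      m[top$cell] <- top$z
      chm <- pmax(chm, m)
      next
    }
    cutoff <- if (t >= 2 && edge_cutoff_factor > 0)
      edge_cutoff_factor * grid$cell_size else 0
    z <- cpp_tin_interp(top$x, top$y, top$z, q$x, q$y, FALSE, cutoff)
    m <- matrix(z, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
    m[is.na(m)] <- -Inf
    chm <- pmax(chm, m)
  }
  chm[!is.finite(chm)] <- 0
  chm[chm < 0] <- 0
  grid$values <- chm
  grid
}

#' Naive single-layer CHM (per-cell highest point)
#'
#' Reference CHM without pit-free layering: each cell takes the height of
#' its highest point, empty cells 0. Used for comparison and as the lower
#' bound that [pitfree_chm()] must dominate.
#'
#' @inheritParams pitfree_chm
#' @return A [raster_grid()] CHM.
#' @export
naive_chm <- function(cloud, resolution, grid = NULL) {
  if (is.null(grid)) grid <- empty_grid_for(cloud, resolution)
  nonground <- if (!is.null(cloud$ground)) cloud[!cloud$ground, , drop = FALSE] else cloud
  idx <- cell_index(grid, nonground$x, nonground$y, clamp = TRUE)
  dt <- data.table::data.table(cell = (idx$col - 1L) * grid$n_rows + idx$row,
                               z = nonground$z)
  top <- dt[, .(z = max(z)), by = cell]
  m <- matrix(0, grid$n_rows, grid$n_cols)
  m[top$cell] <- pmax(top$z, 0)
  grid$values <- m
  grid
}
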