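#' Georeferenced raster grid
#'
#' A `RasterGrid` stores a single-band height raster (DTM or CHM). Values are
#' kept as a numeric matrix with `n_rows` x `n_cols` entries; row 1 is the
#' *southernmost* row internally (y increases with row index) so that matrix
#' indexing follows map coordinates; writers flip to the north-up convention
#' of the raster formats.
#'
#' Cell `(i, j)` covers the half-open square
#' `[origin_x + (j-1)*cs, origin_x + j*cs) x [origin_y + (i-1)*cs, origin_y + i*cs)`
#' and its value refers to the cell center.
#'
#' @param values numeric matrix of cell values (row 1 = southernmost row).
#' @param origin_x,origin_y coordinates of the lower-left corner of the
#'   lower-left cell (meters).
#' @param cell_size cell edge length in meters, > 0.
#' @param nodata sentinel used on export for missing cells (default -9999).
#' @return A `RasterGrid` object.
#' @examples
#' g <- raster_grid(matrix(0, 10, 10), 0, 0, 0.5)
#' dim(g$values)
#' @export
raster_grid <- function(values, origin_x, origin_y, cell_size,
                        nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (cell_size <= 0) stop("cell_size must be > 0")
  g <- list(values = values, origin_x = as.numeric(origin_x),
            origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
            n_rows = nrow(values), n_cols = ncol(values),
            nodata = as.numeric(nodata))
  class(g) <- "RasterGrid"
  g
}

#' @export
print.RasterGrid <- function(x, ...) {
  cat(sprintf("RasterGrid: %d x %d cells, %.3g m resolution\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  origin: (%.3f, %.3f), extent %.1f x %.1f m\n",
              x$origin_x, x$origin_y, x$n_cols * x$cell_size,
              x$n_rows * x$cell_size))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%.3f, %.3f]\n", min(v), max(v)))
  invisible(x)
}

#' Cell center coordinates of a raster grid
#' @param grid a [raster_grid()].
#' @return list with vectors `x` (per column) and `y` (per row).
#' @keywords internal
grid_centers <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

# half-open cell index for point coordinates; clamp = TRUE snaps outside
# points to the border cell
cell_index <- function(grid, x, y, clamp = FALSE) {
  j <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  i <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  if (clamp) {
    i <- pmin(pmax(i, 1L), grid$n_rows)
    j <- pmin(pmax(j, 1L), grid$n_cols)
  }
  list(row = as.integer(i), col = as.integer(j))
}

#' Bilinear sample of a raster at arbitrary coordinates
#'
#' Values are interpreted at cell centers; queries between centers are
#' bilinearly interpolated, queries beyond the outermost centers use the
#' nearest cell (constant extrapolation).
#'
#' @param grid a [raster_grid()].
#' @param x,y query coordinates (meters).
#' @return numeric vector of sampled values.
#' @export
sample_bilinear <- function(grid, x, y) {
  cs <- grid$cell_size
  # fractional cell-center coordinates
  fx <- (x - grid$origin_x) / cs - 0.5
  fy <- (y - grid$origin_y) / cs - 0.5
  j0 <- pmin(pmax(floor(fx), 0), grid$n_cols - 1L)
  i0 <- pmin(pmax(floor(fy), 0), grid$n_rows - 1L)
  j1 <- pmin(j0 + 1, grid$n_cols - 1L)
  i1 <- pmin(i0 + 1, grid$n_rows - 1L)
  tx <- pmin(pmax(fx - j0, 0), 1)
  ty <- pmin(pmax(fy - i0, 0), 1)
  v <- grid$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  (1 - ty) * ((1 - tx) * idx(i0, j0) + tx * idx(i0, j1)) +
    ty * ((1 - tx) * idx(i1, j0) + tx * idx(i1, j1))
}
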