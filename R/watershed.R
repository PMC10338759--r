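#' Watershed parameters
#'
#' @param tolerance minimum seed-to-contact height drop (meters) below which
#'   an object is merged into its highest neighbor (default 1).
#' @param ext neighborhood radius in pixels for seed detection; local maxima
#'   are detected in a `(2*ext+1)^2` window (default 2).
#' @param min_height background cutoff (meters); CHM pixels at or below this
#'   height are background (default 2).
#' @return parameter list.
#' @export
watershed_params <- function(tolerance = 1, ext = 2L, min_height = 2) {
  stopifnot(tolerance >= 0, ext >= 1)
  list(tolerance = tolerance, ext = as.integer(ext), min_height = min_height)
}

# matrix shifted by (dr, dc), vacated cells = fill
shift_mat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Detect tree-top seeds in a CHM
#'
#' Seeds are local height maxima within a `(2*ext+1)^2` pixel window, above
#' `min_height`. Plateau ties keep only the pixel with the smallest
#' (row, col) among the window pixels attaining the maximum.
#'
#' @param chm a [raster_grid()] canopy height model.
#' @param params [watershed_params()].
#' @return data frame with `row`, `col`, `z` per seed, ordered by (row, col).
#' @export
detect_seeds <- function(chm, params = watershed_params()) {
  z <- chm$values
  nr <- nrow(z); nc <- ncol(z)
  ridx <- matrix(rep(seq_len(nr), nc), nr, nc)
  cidx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ord <- (ridx - 1) * nc + cidx          # row-major order index
  ext <- params$ext
  winmax <- matrix(-Inf, nr, nc)
  winfirst <- matrix(Inf, nr, nc)        # min order index attaining winmax
  for (dr in -ext:ext) {
    for (dc in -ext:ext) {
      sz <- shift_mat(z, dr, dc, fill = -Inf)
      so <- shift_mat(ord, dr, dc, fill = Inf)
      better <- sz > winmax
      tie <- sz == winmax & so < winfirst
      winfirst[better | tie] <- so[better | tie]
      winmax[better] <- sz[better]
    }
  }
  seed <- z > params$min_height & z == winmax & ord == winfirst
  idx <- which(seed)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  o <- order(row, col)
  data.frame(row = row[o], col = col[o], z = z[cbind(row[o], col[o])])
}

#' Watershed segmentation of a CHM with tolerance merging
#'
#' Floods the CHM from the detected seeds by descending height
#' (8-connectivity, deterministic tie-breaks), then iteratively merges any
#' object whose height drop between its highest point and its highest
#' contact pixel with a neighboring object is smaller than `tolerance` into
#' its highest neighbor, until stable. Labels are renumbered contiguously
#' from 1 in (row, col) order of their highest pixel.
#'
#' @param chm a [raster_grid()].
#' @param params [watershed_params()].
#' @return A `SegmentMap`: list with `labels` (integer matrix aligned to the
#'   CHM), the `grid` template, `params`, and `n_segments`.
#' @export
watershed_segment <- function(chm, params = watershed_params()) {
  seeds <- detect_seeds(chm, params)
  z <- chm$values
  if (nrow(seeds) == 0L) {
    lab <- matrix(0L, nrow(z), ncol(z))
  } else {
    lab <- cpp_watershed_flood(z, seeds$row, seeds$col, params$min_height)
    lab <- merge_tolerance(z, lab, params$tolerance)
  }
  lab <- relabel_rowmajor(z, lab)
  structure(list(labels = lab, grid = chm, params = params,
                 n_segments = max(lab)), class = "SegmentMap")
}

#' @export
print.SegmentMap <- function(x, ...) {
  cat(sprintf("SegmentMap: %d segments over %d x %d cells\n",
              x$n_segments, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# iterative tolerance merge; weakest (lowest) objects merge first
merge_tolerance <- function(z, lab, tolerance) {
  if (tolerance <= 0) return(lab)
  repeat {
    labs <- sort(setdiff(unique(as.vector(lab)), 0L))
    if (length(labs) < 2L) return(lab)
    top <- vapply(labs, function(l) max(z[lab == l]), numeric(1))
    names(top) <- labs
    # adjacency contacts via 8-neighbor shifts
    contact <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- shift_mat(lab, dr, dc, fill = 0L)
      sel <- lab != 0L & nb != 0L & lab != nb
      if (!any(sel)) next
      contact[[length(contact) + 1L]] <-
        data.frame(a = lab[sel], b = nb[sel], cz = z[sel])
    }
    if (!length(contact)) return(lab)
    con <- do.call(rbind, contact)
    dt <- data.table::as.data.table(con)
    # per object: highest contact pixel with any neighboring object
    hc <- dt[, .(cz = max(cz)), by = a]
    drop_h <- top[as.character(hc$a)] - hc$cz
    cand <- hc$a[drop_h < tolerance]
    if (!length(cand)) return(lab)
    # weakest candidate first
    a <- cand[which.min(top[as.character(cand)])]
    nbs <- unique(dt$b[dt$a == a])
    target <- nbs[which.max(top[as.character(nbs)])]
    lab[lab == a] <- target
  }
}

# contiguous labels 1..m ordered by (row, col) of each segment's highest pixel
relabel_rowmajor <- function(z, lab) {
  labs <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(labs)) return(lab)
  nr <- nrow(lab)
  key <- vapply(labs, function(l) {
    idx <- which(lab == l)
    zi <- z[idx]
    cand <- idx[zi == max(zi)]
    row <- (cand - 1L) %% nr + 1L
    col <- (cand - 1L) %/% nr + 1L
    o <- order(row, col)[1]
    (row[o] - 1) * ncol(lab) + col[o]
  }, numeric(1))
  newlab <- match(lab, labs[order(key)])
  newlab[is.na(newlab)] <- 0L
  matrix(as.integer(newlab), nrow(lab), ncol(lab))
}

#' Project segment labels onto points
#'
#' Each point at or above `min_height` receives the label of the CHM pixel
#' containing it (half-open cell intervals); background pixels and points
#' below the cutoff get label 0.
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param seg a `SegmentMap` from [watershed_segment()].
#' @return The cloud with a `tree_label` column.
#' @export
label_points <- function(cloud, seg) {
  grid <- seg$grid
  idx <- cell_index(grid, cloud$x, cloud$y)
  inside <- idx$row >= 1L & idx$row <= grid$n_rows &
    idx$col >= 1L & idx$col <= grid$n_cols
  labels <- integer(nrow(cloud))
  ok <- inside & cloud$z >= seg$params$min_height
  labels[ok] <- seg$labels[cbind(idx$row[ok], idx$col[ok])]
  cloud$tree_label <- labels
  cloud
}
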