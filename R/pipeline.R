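#' Segment individual trees from a point cloud
#'
#' Runs the full pipeline: ground classification (pass-through when the
#' cloud is pre-classified), TIN DTM, height normalization, pit-free CHM,
#' watershed initial segmentation with tolerance merging, then per-segment
#' refinement — mean-shift voxelization, a connection-center-evolution
#' sweep over connectivity scales, and tri-planar scale selection — and
#' finally the plantation merge rule and per-tree attribute extraction.
#'
#' @param cloud a [point_cloud()] (absolute elevations; ground flags used
#'   if present).
#' @param config a [run_config()].
#' @param verbose log per-stage progress to stderr.
#' @return list with `cloud` (height-normalized, labeled), `trees` (list of
#'   `TreeRecord`), `tree_table` (a [tree_table()]), `chm`, `dtm`, and
#'   `segments` (the initial `SegmentMap`).
#' @export
segment_trees <- function(cloud, config = run_config(), verbose = FALSE) {
  log_stage <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_stage("[%s] done at %.1fs", name, proc.time()[3] - t0)
    r
  }

  cloud <- stage("ground", classify_ground(cloud, config$ground$grid_size,
                                           config$ground$band))
  density <- canopy_density(cloud)
  resolution <- config$raster$resolution
  if (is.null(resolution)) resolution <- if (density >= 100) 0.1 else 0.2
  log_stage("[density] %.0f pts/m2 over canopy footprint; resolution %.2g m",
            density, resolution)
  dtm <- stage("dtm", build_dtm(cloud, resolution))
  norm <- stage("normalize", normalize_heights(cloud, dtm))
  chm <- stage("chm", pitfree_chm(norm, resolution,
                                  layers = config$raster$layers,
                                  edge_cutoff_factor = config$raster$edge_cutoff_factor))
  params <- watershed_params(config$watershed$tolerance,
                             config$watershed$ext,
                             config$watershed$min_height)
  seg <- stage("watershed", watershed_segment(chm, params))
  log_stage("[watershed] %d initial segments", seg$n_segments)
  norm <- stage("label", label_points(norm, seg))

  if (isTRUE(config$cce$enabled) && seg$n_segments > 0L) {
    norm <- stage("cce", refine_segments(norm, config, density))
  }
  if (!any(norm$tree_label > 0L)) {
    log_stage("[done] no trees found")
    return(list(cloud = norm, trees = list(), tree_table = tree_table(),
                chm = chm, dtm = dtm, segments = seg))
  }
  trees <- stage("attributes", extract_tree_attributes(norm))
  if (isTRUE(config$merge$enabled)) {
    n_before <- length(trees)
    trees <- stage("merge", merge_close_trees(
      trees, norm, merge_params(TRUE, config$merge$height_gap_max,
                                config$merge$crown_diameter)))
    log_stage("[merge] %d -> %d trees", n_before, length(trees))
  }
  norm <- apply_tree_labels(norm, trees)
  log_stage("[done] %d trees in %.1fs", length(trees), proc.time()[3] - t0)
  list(cloud = norm, trees = trees, tree_table = trees_to_table(trees),
       chm = chm, dtm = dtm, segments = seg)
}

# voxelize one segment, adapting the bandwidth until the point-to-voxel
# reduction factor falls in the published ~10x operating band [5, 20]:
# voxel weights far above ~10 inflate the weighted pair distances until
# cross-similarities underflow and the connectivity graph disconnects
voxelize_to_band <- function(pts, bandwidth, config) {
  vox <- function(bw) meanshift_voxelize(pts, bw, vr = config$cce$vr,
                                         tol = config$voxel$tol,
                                         max_iter = config$voxel$max_iter)
  sp <- vox(bandwidth)
  if (nrow(pts) < 100L) return(sp)
  for (i in 1:4) {
    reduction <- nrow(pts) / nrow(sp$centers)
    if (reduction > 20 && bandwidth > 0.1) bandwidth <- bandwidth * 0.7
    else if (reduction < 5 && bandwidth < 2) bandwidth <- bandwidth * 1.4
    else break
    sp <- vox(bandwidth)
  }
  sp
}

# sampling density of the non-ground returns over their occupied 1 m
# footprint (pts/m2); robust to bare ground dominating the plot extent
canopy_density <- function(cloud) {
  ng <- cloud[!cloud$ground, , drop = FALSE]
  if (nrow(ng) == 0L) return(0)
  cells <- unique(paste(floor(ng$x), floor(ng$y)))
  nrow(ng) / length(cells)
}

# per-segment CCE refinement: voxelize, sweep scales, select, split labels
refine_segments <- function(norm, config, density) {
  bandwidth <- config$voxel$bandwidth
  if (is.null(bandwidth)) bandwidth <- auto_bandwidth(density)
  labs <- sort(setdiff(unique(norm$tree_label), 0L))
  if (!length(labs)) return(norm)
  next_label <- max(labs) + 1L
  ccfg <- cce_config(config$cce$vr, config$cce$sigma, config$cce$max_power,
                     config$cce$weight_mode)
  for (l in labs) {
    idx <- which(norm$tree_label == l)
    pts <- norm[idx, , drop = FALSE]
    sp <- voxelize_to_band(pts, bandwidth, config)
    if (nrow(sp$centers) < config$cce$min_super_points) next
    results <- cce_sweep(sp, ccfg)
    sel <- select_scale(results, sp, pts,
                        edge_fraction = config$scale$edge_fraction)
    if (is.null(sel) || sel$m <= 1L) next
    point_cluster <- sel$assignment[sp$member_map]
    clusters <- unique(point_cluster)
    for (ci in seq_along(clusters)) {
      if (ci == 1L) next                       # first cluster keeps label l
      norm$tree_label[idx[point_cluster == clusters[ci]]] <- next_label
      next_label <- next_label + 1L
    }
  }
  # renumber contiguously, ordered by each tree's top position
  labs <- sort(setdiff(unique(norm$tree_label), 0L))
  norm$tree_label <- match(norm$tree_label, labs, nomatch = 0L)
  norm$tree_label[is.na(norm$tree_label)] <- 0L
  norm
}
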