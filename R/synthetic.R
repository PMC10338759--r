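#' Synthetic forest specification
#'
#' Parameters of the deterministic forest generator used for offline
#' validation. Defaults emulate a mid-density coniferous ULS plot: a 30 x 30
#' m stand at 0.05 stems/m2 of cone crowns 13--25 m tall on gently sloped
#' terrain, sampled at 300 pts/m2 with exponential thinning below each apex
#' to mimic canopy occlusion.
#'
#' @param plot_size c(width, height) in meters.
#' @param stem_density trees per m2.
#' @param crown_shape `"cone"`, `"ellipsoid"` or `"mixed"`.
#' @param height_range c(min, max) apex height in meters.
#' @param crown_radius_range c(min, max) crown radius in meters.
#' @param slope_deg terrain slope along x in degrees.
#' @param point_density crown sampling density in pts/m2 (of projected crown
#'   area).
#' @param occlusion_decay per-meter retention decay below the apex
#'   (retention probability `exp(-occlusion_decay * depth)`).
#' @param min_spacing minimum stem-to-stem distance in meters.
#' @param seed integer RNG seed; all stochastic choices derive from it.
#' @return validated specification list.
#' @export
forest_spec <- function(plot_size = c(30, 30), stem_density = 0.05,
                        crown_shape = c("cone", "ellipsoid", "mixed"),
                        height_range = c(13, 25),
                        crown_radius_range = c(1.2, 1.8),
                        slope_deg = 5, point_density = 300,
                        occlusion_decay = 0.15, min_spacing = 3,
                        seed = 1L) {
  crown_shape <- match.arg(crown_shape)
  stopifnot(stem_density > 0, point_density > 0, min_spacing >= 0,
            height_range[1] > 0, height_range[2] >= height_range[1],
            crown_radius_range[1] > 0)
  list(plot_size = plot_size, stem_density = stem_density,
       crown_shape = crown_shape, height_range = height_range,
       crown_radius_range = crown_radius_range, slope_deg = slope_deg,
       point_density = point_density, occlusion_decay = occlusion_decay,
       min_spacing = min_spacing, seed = as.integer(seed))
}

terrain_z <- function(spec, x, y) {
  tan(spec$slope_deg * pi / 180) * x +
    0.15 * sin(2 * pi * x / 17) * cos(2 * pi * y / 23)
}

# sample one crown; apex point is always emitted first and never thinned
sample_crown <- function(spec, shape, x0, y0, apex_z, h, r) {
  n <- max(1L, round(spec$point_density * pi * r^2))
  depth_max <- 0.6 * h                  # live crown depth
  u <- runif(n)^(1 / 3)                 # depth fraction, volume-weighted
  depth <- u * depth_max
  theta <- runif(n, 0, 2 * pi)
  if (shape == "cone") {
    renv <- r * u                       # envelope radius grows with depth
  } else {
    b <- depth_max / 2                  # vertical semi-axis
    renv <- r * sqrt(pmax(0, 1 - ((depth - b) / b)^2))
  }
  rad <- renv * sqrt(runif(n))          # volumetric fill of each slice
  keep <- runif(n) < exp(-spec$occlusion_decay * depth)
  px <- x0 + rad * cos(theta)
  py <- y0 + rad * sin(theta)
  pz <- apex_z - depth
  data.frame(x = c(x0, px[keep]), y = c(y0, py[keep]),
             z = c(apex_z, pz[keep]))
}

#' Generate a synthetic forest plot with ground truth
#'
#' Builds sloped terrain with low-amplitude undulation, places
#' `round(stem_density * area)` stems on a jittered grid honoring
#' `min_spacing`, samples each crown (cone or ellipsoid envelope) at the
#' requested point density with exponential occlusion thinning below the
#' apex (the apex point itself is always retained), and adds ground returns
#' at a tenth of the crown density. Fully reproducible from `spec$seed`.
#'
#' @param spec a [forest_spec()].
#' @return list with `cloud` (a ground-flagged [point_cloud()], absolute
#'   elevations) and `truth` (a [tree_table()]; heights are normalized apex
#'   heights, exactly as drawn).
#' @export
generate_forest <- function(spec = forest_spec()) {
  withr::with_seed(spec$seed, generate_forest_impl(spec))
}

generate_forest_impl <- function(spec) {
  w <- spec$plot_size[1]; h <- spec$plot_size[2]
  area <- w * h
  n_trees <- round(spec$stem_density * area)
  if (n_trees < 1) stop("spec error: density * area rounds to zero trees")
  # jittered grid placement
  pitch <- sqrt(area / n_trees)
  nx <- ceiling(w / pitch); ny <- ceiling(h / pitch)
  wx <- w / nx; wy <- h / ny                  # actual grid cell sizes
  if (min(wx, wy) < spec$min_spacing)
    stop("spec error: cannot place ", n_trees, " stems with min_spacing ",
         spec$min_spacing)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  # jitter bounded so adjacent stems stay >= min_spacing apart
  jit_x <- min((wx - spec$min_spacing) / 2, 0.35 * wx)
  jit_y <- min((wy - spec$min_spacing) / 2, 0.35 * wy)
  cx <- (cells$ix - 0.5) * wx
  cy <- (cells$iy - 0.5) * wy
  keep <- sample.int(nrow(cells), n_trees)
  sx <- cx[keep] + runif(n_trees, -jit_x, jit_x)
  sy <- cy[keep] + runif(n_trees, -jit_y, jit_y)
  heights <- runif(n_trees, spec$height_range[1], spec$height_range[2])
  radii <- runif(n_trees, spec$crown_radius_range[1],
                 spec$crown_radius_range[2])
  shapes <- switch(spec$crown_shape,
                   cone = rep("cone", n_trees),
                   ellipsoid = rep("ellipsoid", n_trees),
                   mixed = sample(c("cone", "ellipsoid"), n_trees,
                                  replace = TRUE))
  crowns <- lapply(seq_len(n_trees), function(i) {
    tz <- terrain_z(spec, sx[i], sy[i])
    sample_crown(spec, shapes[i], sx[i], sy[i], tz + heights[i],
                 heights[i], radii[i])
  })
  crown_pts <- do.call(rbind, crowns)
  n_ground <- max(3L, round(spec$point_density / 10 * area))
  gx <- runif(n_ground, 0, w)
  gy <- runif(n_ground, 0, h)
  gz <- terrain_z(spec, gx, gy) + rnorm(n_ground, 0, 0.02)
  cloud <- point_cloud(c(crown_pts$x, gx), c(crown_pts$y, gy),
                       c(crown_pts$z, gz),
                       ground = c(rep(FALSE, nrow(crown_pts)),
                                  rep(TRUE, n_ground)))
  truth <- tree_table(seq_len(n_trees), sx, sy, heights)
  list(cloud = cloud, truth = truth, spec = spec)
}

#' Generate a single bifurcated tree
#'
#' One ground-truth tree whose crown carries two apices separated by less
#' than one crown radius — the trunk-bifurcation pattern that splits a
#' single larch into two detections. Used to exercise the close-tree merge
#' rule and over-segmentation reporting.
#'
#' @param spec a [forest_spec()]; plot size, densities and terrain are
#'   reused, tree placement is fixed at the plot center.
#' @param apex_offset horizontal distance between the two apices (meters,
#'   default 1.2; must stay below the crown radius used, 1.6 m).
#' @param height_drop height of the secondary apex below the main one
#'   (meters, default 1.0).
#' @return list with `cloud`, `truth` (a single reference tree at the main
#'   apex) and `spec`.
#' @export
generate_bifurcated_tree <- function(spec = forest_spec(), apex_offset = 1.2,
                                     height_drop = 1.0) {
  withr::with_seed(spec$seed + 1L, {
    w <- spec$plot_size[1]; h <- spec$plot_size[2]
    x0 <- w / 2; y0 <- h / 2
    height <- mean(spec$height_range)
    r <- 1.6
    tz <- terrain_z(spec, x0, y0)
    main <- sample_crown(spec, "cone", x0, y0, tz + height, height, r)
    sec <- sample_crown(spec, "cone", x0 + apex_offset, y0,
                        tz + height - height_drop, height - height_drop, r)
    crown <- rbind(main, sec)
    n_ground <- max(3L, round(spec$point_density / 10 * w * h))
    gx <- runif(n_ground, 0, w)
    gy <- runif(n_ground, 0, h)
    gz <- terrain_z(spec, gx, gy) + rnorm(n_ground, 0, 0.02)
    cloud <- point_cloud(c(crown$x, gx), c(crown$y, gy), c(crown$z, gz),
                         ground = c(rep(FALSE, nrow(crown)),
                                    rep(TRUE, n_ground)))
    list(cloud = cloud, truth = tree_table(1L, x0, y0, height), spec = spec)
  })
}
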