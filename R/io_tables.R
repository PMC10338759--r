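#' Tree tables
#'
#' A `TreeTable` is a data frame with columns `tree_id`, `x`, `y`, `height`
#' (meters), one row per detected or reference tree. `tree_id` must be
#' unique and heights positive.
#'
#' @param tree_id integer ids (unique).
#' @param x,y tree top coordinates (meters).
#' @param height tree height (meters, > 0).
#' @return A `TreeTable` data frame.
#' @export
tree_table <- function(tree_id = integer(), x = numeric(), y = numeric(),
                       height = numeric()) {
  tt <- data.frame(tree_id = as.integer(tree_id), x = as.numeric(x),
                   y = as.numeric(y), height = as.numeric(height))
  validate_tree_table(tt)
  class(tt) <- c("TreeTable", "data.frame")
  tt
}

validate_tree_table <- function(tt) {
  if (anyDuplicated(tt$tree_id)) stop("tree_id values must be unique")
  if (nrow(tt) && any(tt$height <= 0)) stop("tree heights must be > 0")
  invisible(tt)
}

#' Read / write tree tables as CSV
#'
#' The CSV schema is `tree_id,x,y,height` with a header row; an empty table
#' round-trips as a header-only file.
#'
#' @param path CSV file path.
#' @return [read_tree_table()]: a [tree_table()].
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stop("cannot read tree table: file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("tree_id", "x", "y", "height")
  if (!all(need %in% names(df)))
    stop("tree table must have columns tree_id,x,y,height: ", path)
  tree_table(df$tree_id, df$x, df$y, df$height)
}

#' @param trees a [tree_table()] (or data frame with the same columns).
#' @rdname read_tree_table
#' @export
write_tree_table <- function(trees, path) {
  df <- as.data.frame(trees)[, c("tree_id", "x", "y", "height")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Returns the full default configuration of the segmentation pipeline as a
#' nested list; `...` overrides individual entries (by name at the top level
#' of each group). Defaults follow the method's published settings: watershed
#' `tolerance` 1 m and `ext` 2 px, vertical distance correction `vr` = 1/6,
#' Gaussian kernel scale `sigma` = 30, pit-free layer thresholds
#' 0/2/5/10/15 m, and top-edge distance fraction 1/8.
#'
#' @param ... named groups to override, e.g. `cce = list(sigma = 10)`.
#' @return nested configuration list.
#' @examples
#' cfg <- run_config(cce = list(sigma = 10))
#' cfg$cce$sigma
#' @export
run_config <- function(...) {
  cfg <- list(
    raster = list(resolution = NULL,    # NULL = auto by point density
                  layers = c(0, 2, 5, 10, 15),
                  edge_cutoff_factor = 3),
    ground = list(grid_size = 1, band = 0.2),
    watershed = list(tolerance = 1, ext = 2L, min_height = 2),
    voxel = list(bandwidth = NULL,      # NULL = auto by point density
                 max_iter = 100L, tol = 1e-3),
    cce = list(vr = 1 / 6, sigma = 30, max_power = 2^20,
               weight_mode = "printed", min_super_points = 10L,
               enabled = TRUE),
    scale = list(edge_fraction = 1 / 8),
    merge = list(enabled = TRUE, height_gap_max = 10, crown_diameter = NULL),
    match = list(max_xy_dist = 5, max_rel_height_diff = 0.2),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config group: ", nm)
    if (is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) {
        if (!k %in% names(cfg[[nm]]))
          stop("unknown config key: ", nm, ".", k)
        cfg[[nm]][[k]] <- over[[nm]][[k]]
      }
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$watershed$tolerance >= 0, cfg$watershed$ext >= 1,
            cfg$cce$vr > 0, cfg$cce$vr <= 1, cfg$cce$sigma > 0,
            cfg$scale$edge_fraction > 0, cfg$scale$edge_fraction < 0.5,
            cfg$merge$height_gap_max > 0)
  if (!cfg$cce$weight_mode %in% c("printed", "none"))
    stop("cce.weight_mode must be 'printed' or 'none'")
  cfg
}

#' Read / write run configuration as YAML
#' @param path YAML file path.
#' @return [read_config()]: validated configuration list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @param config configuration list from [run_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
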