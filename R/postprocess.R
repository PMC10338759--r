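#' Extract per-tree attributes from a labeled cloud
#'
#' One record per tree label >= 1: the tree top is the member point with the
#' maximal normalized height (its height and coordinates become the tree's),
#' crown widths are the per-label x/y extents.
#'
#' @param cloud a labeled, height-normalized [point_cloud()].
#' @return list of `TreeRecord`: each a list with `tree_id`, `top_x`,
#'   `top_y`, `height`, `crown_x`, `crown_y` and integer `members` (point
#'   row indices).
#' @export
extract_tree_attributes <- function(cloud) {
  if (is.null(cloud$tree_label)) stop("cloud has no tree labels")
  labs <- sort(setdiff(unique(cloud$tree_label), 0L))
  lapply(seq_along(labs), function(i) {
    members <- which(cloud$tree_label == labs[i])
    p <- cloud[members, , drop = FALSE]
    top <- members[which.max(p$z)]
    structure(list(tree_id = i,
                   top_x = cloud$x[top], top_y = cloud$y[top],
                   height = cloud$z[top],
                   crown_x = max(p$x) - min(p$x),
                   crown_y = max(p$y) - min(p$y),
                   members = members), class = "TreeRecord")
  })
}

#' Merge parameters for plantation-like plots
#'
#' @param enabled run the merge at all (default TRUE).
#' @param height_gap_max maximum height difference between two tree tops for
#'   them to be merge candidates (meters, default 10).
#' @param crown_diameter horizontal top-to-top distance threshold (meters);
#'   `NULL` (default) auto-computes the plot's mean crown diameter as the
#'   mean of `(crown_x + crown_y)/2` over the current records.
#' @return parameter list.
#' @export
merge_params <- function(enabled = TRUE, height_gap_max = 10,
                         crown_diameter = NULL) {
  stopifnot(height_gap_max > 0)
  list(enabled = enabled, height_gap_max = height_gap_max,
       crown_diameter = crown_diameter)
}

#' Merge spuriously split trees
#'
#' Iteratively merges the pair of trees with the smallest horizontal
#' top-to-top distance among pairs that are closer than the (plot-average or
#' user-set) crown diameter and whose height difference is below
#' `height_gap_max`. Members are united, attributes re-extracted from the
#' union, and the search repeats until no pair qualifies. Intended for
#' plantation-like stands where bifurcated trunks split one crown into two
#' detections.
#'
#' @param trees list of `TreeRecord` from [extract_tree_attributes()].
#' @param cloud the labeled cloud the records came from.
#' @param params [merge_params()].
#' @return list of `TreeRecord` with contiguous ids.
#' @export
merge_close_trees <- function(trees, cloud, params = merge_params()) {
  if (!params$enabled || length(trees) < 2L) return(trees)
  repeat {
    n <- length(trees)
    if (n < 2L) break
    cd <- params$crown_diameter
    if (is.null(cd))
      cd <- mean(vapply(trees, function(t) (t$crown_x + t$crown_y) / 2,
                        numeric(1)))
    tops_x <- vapply(trees, `[[`, numeric(1), "top_x")
    tops_y <- vapply(trees, `[[`, numeric(1), "top_y")
    hts <- vapply(trees, `[[`, numeric(1), "height")
    dist <- as.matrix(stats::dist(cbind(tops_x, tops_y)))
    dh <- abs(outer(hts, hts, "-"))
    ok <- dist < cd & dh < params$height_gap_max
    diag(ok) <- FALSE
    ok[lower.tri(ok)] <- FALSE
    if (!any(ok)) break
    cand <- which(ok, arr.ind = TRUE)
    d <- dist[cand]
    # smallest distance first; ties by (i, j)
    o <- order(d, cand[, 1], cand[, 2])[1]
    i <- cand[o, 1]; j <- cand[o, 2]
    members <- sort(c(trees[[i]]$members, trees[[j]]$members))
    p <- cloud[members, , drop = FALSE]
    top <- members[which.max(p$z)]
    merged <- structure(list(tree_id = trees[[i]]$tree_id,
                             top_x = cloud$x[top], top_y = cloud$y[top],
                             height = cloud$z[top],
                             crown_x = max(p$x) - min(p$x),
                             crown_y = max(p$y) - min(p$y),
                             members = members), class = "TreeRecord")
    trees[[i]] <- merged
    trees[[j]] <- NULL
  }
  for (i in seq_along(trees)) trees[[i]]$tree_id <- i
  trees
}

#' Tree records as a tree table
#'
#' @param trees list of `TreeRecord`.
#' @return a [tree_table()] (`tree_id`, `x`, `y`, `height`).
#' @export
trees_to_table <- function(trees) {
  if (!length(trees)) return(tree_table())
  tree_table(tree_id = vapply(trees, `[[`, numeric(1), "tree_id"),
             x = vapply(trees, `[[`, numeric(1), "top_x"),
             y = vapply(trees, `[[`, numeric(1), "top_y"),
             height = vapply(trees, `[[`, numeric(1), "height"))
}

# rewrite cloud labels from a record list (after merging)
apply_tree_labels <- function(cloud, trees) {
  labels <- integer(nrow(cloud))
  for (t in trees) labels[t$members] <- t$tree_id
  cloud$tree_label <- labels
  cloud
}
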