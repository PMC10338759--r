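#' Match detected trees to reference trees
#'
#' Detected trees are processed from tallest to shortest. For each, the
#' match candidates are the reference trees within `max_xy_dist` meters
#' whose relative height difference (|dh| / reference height) is at most
#' `max_rel_height_diff`; among candidates the one with the smallest
#' absolute height difference wins, with horizontal distance breaking
#' height ties — so a farther candidate with a better height agreement is
#' preferred over a nearer one. A reference tree already matched can be
#' displaced by a detection with a better height agreement; the displaced
#' detection then retries its remaining candidates (stable re-assignment
#' loop). The pairing is one-to-one.
#'
#' @param detected,reference [tree_table()]s.
#' @param params [match_params()].
#' @return list with `pairs` (data frame `detected_id`, `reference_id`,
#'   `distance`, `dh`), and counts `TP`, `FP`, `FN`.
#' @export
match_trees <- function(detected, reference, params = match_params()) {
  if (nrow(reference) == 0L) stop("evaluation error: empty reference table")
  nd <- nrow(detected); nr <- nrow(reference)
  # per-detection candidate lists ordered by preference (dh, then distance)
  dist <- outer(detected$x, reference$x, "-")^2 +
    outer(detected$y, reference$y, "-")^2
  dist <- sqrt(dist)
  dh <- abs(outer(detected$height, reference$height, "-"))
  ok <- dist <= params$max_xy_dist &
    sweep(dh, 2, reference$height, "/") <= params$max_rel_height_diff
  prefs <- lapply(seq_len(nd), function(i) {
    cand <- which(ok[i, ])
    cand[order(dh[i, cand], dist[i, cand])]
  })
  ref_match <- rep(NA_integer_, nr)   # detected index per reference
  tried <- lapply(seq_len(nd), function(i) integer(0))
  queue <- order(-detected$height, detected$tree_id)
  guard <- 100L * max(nd, 1L)
  while (length(queue) && guard > 0L) {
    guard <- guard - 1L
    i <- queue[1]; queue <- queue[-1]
    cand <- setdiff(prefs[[i]], tried[[i]])
    assigned <- FALSE
    for (j in cand) {
      tried[[i]] <- c(tried[[i]], j)
      cur <- ref_match[j]
      if (is.na(cur)) {
        ref_match[j] <- i
        assigned <- TRUE
        break
      }
      # reference keeps the detection with the better height agreement
      better <- dh[i, j] < dh[cur, j] ||
        (dh[i, j] == dh[cur, j] && dist[i, j] < dist[cur, j])
      if (better) {
        ref_match[j] <- i
        queue <- c(queue, cur)          # displaced detection retries
        assigned <- TRUE
        break
      }
    }
    if (!assigned) next                 # unmatched: commission error
  }
  matched <- which(!is.na(ref_match))
  pairs <- data.frame(
    detected_id = detected$tree_id[ref_match[matched]],
    reference_id = reference$tree_id[matched],
    distance = dist[cbind(ref_match[matched], matched)],
    dh = dh[cbind(ref_match[matched], matched)])
  pairs <- pairs[order(-detected$height[ref_match[matched]]), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, TP = nrow(pairs),
       FP = nrow(detected) - nrow(pairs),
       FN = nrow(reference) - nrow(pairs))
}

#' @param max_xy_dist maximum horizontal top-to-top distance for a match
#'   (meters, default 5).
#' @param max_rel_height_diff maximum relative height difference for a
#'   match (fraction of the reference height, default 0.2).
#' @rdname match_trees
#' @export
match_params <- function(max_xy_dist = 5, max_rel_height_diff = 0.2) {
  stopifnot(max_xy_dist > 0, max_rel_height_diff > 0)
  list(max_xy_dist = max_xy_dist, max_rel_height_diff = max_rel_height_diff)
}

#' Detection metrics from match counts
#'
#' The five treetop detection metrics:
#' `R_extraction = (TP+FP)/(TP+FN)`, `R_match = TP/(TP+FN)`,
#' `R_commission = FP/(TP+FP)`, `R_omission = FN/(TP+FN)`, and the F-score,
#' the harmonic mean of the matching rate (recall) and the precision
#' `R_match / R_extraction = TP/(TP+FP)`.
#'
#' @param TP,FP,FN non-negative integer counts; `TP + FN` (the reference
#'   tree count) must be positive.
#' @return named list with the five metrics.
#' @examples
#' compute_detection_metrics(3, 1, 1)
#' @export
compute_detection_metrics <- function(TP, FP, FN) {
  if (TP + FN <= 0) stop("reference count TP + FN must be positive")
  r_extraction <- (TP + FP) / (TP + FN)
  r_match <- TP / (TP + FN)
  if (TP + FP == 0) {
    warning("no detected trees; commission rate reported as 0")
    r_commission <- 0
  } else {
    r_commission <- FP / (TP + FP)
  }
  r_omission <- FN / (TP + FN)
  if (TP == 0) {
    f <- 0
  } else {
    precision <- TP / (TP + FP)
    f <- 2 * r_match * precision / (r_match + precision)
  }
  list(R_match = r_match, R_extraction = r_extraction, F = f,
       R_omission = r_omission, R_commission = r_commission)
}

#' Detection metrics from printed rates
#'
#' Recovers the remaining metrics from a (matching rate, extraction rate)
#' pair via the algebraic identities `precision = R_match / R_extraction`,
#' `R_commission = 1 - precision`, `R_omission = 1 - R_match` and the
#' harmonic-mean F-score. Useful for cross-checking published result
#' tables that only print rates.
#'
#' @param r_match matching rate in (0, 1].
#' @param r_extraction extraction rate (> 0).
#' @return named list with `R_match`, `R_extraction`, `F`, `R_omission`,
#'   `R_commission`.
#' @examples
#' metrics_from_rates(0.61, 0.80)$F   # 0.678 -> prints as 0.68
#' @export
metrics_from_rates <- function(r_match, r_extraction) {
  stopifnot(all(r_match >= 0), all(r_extraction > 0))
  precision <- r_match / r_extraction
  f <- ifelse(r_match + precision > 0,
              2 * r_match * precision / (r_match + precision), 0)
  list(R_match = r_match, R_extraction = r_extraction, F = f,
       R_omission = 1 - r_match, R_commission = 1 - precision)
}

#' Height accuracy of matched pairs
#'
#' Coefficient of determination and root mean square error of detected
#' versus reference heights over the matched pairs:
#' `R^2 = 1 - SS_res / SS_tot` with the reference heights as truth.
#'
#' @param detected_height,reference_height equal-length numeric vectors
#'   (>= 2 pairs).
#' @return list with `r2` and `rmse` (meters).
#' @export
height_accuracy <- function(detected_height, reference_height) {
  n <- length(detected_height)
  if (n < 2L) stop("need at least 2 matched pairs")
  stopifnot(length(reference_height) == n)
  ss_tot <- sum((reference_height - mean(reference_height))^2)
  if (ss_tot == 0) stop("zero height variance in reference trees")
  resid <- detected_height - reference_height
  list(r2 = 1 - sum(resid^2) / ss_tot, rmse = sqrt(mean(resid^2)))
}

#' Full evaluation report
#'
#' Matches detected against reference trees, computes the five detection
#' metrics and (when two or more pairs matched) the height accuracy.
#'
#' @inheritParams match_trees
#' @return list with `TP`, `FP`, `FN`, `pairs`, `metrics`, `height_r2`,
#'   `height_rmse` (the latter `NA` with fewer than 2 pairs).
#' @export
evaluate_detection <- function(detected, reference, params = match_params()) {
  m <- match_trees(detected, reference, params)
  metrics <- compute_detection_metrics(m$TP, m$FP, m$FN)
  r2 <- rmse <- NA_real_
  if (nrow(m$pairs) >= 2L) {
    dh <- detected$height[match(m$pairs$detected_id, detected$tree_id)]
    rh <- reference$height[match(m$pairs$reference_id, reference$tree_id)]
    acc <- tryCatch(height_accuracy(dh, rh), error = function(e) NULL)
    if (!is.null(acc)) { r2 <- acc$r2; rmse <- acc$rmse }
  }
  list(TP = m$TP, FP = m$FP, FN = m$FN, pairs = m$pairs, metrics = metrics,
       height_r2 = r2, height_rmse = rmse)
}
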