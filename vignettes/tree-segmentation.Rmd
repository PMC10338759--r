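---
title: "Individual tree segmentation by watershed and connection-center evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual tree segmentation by watershed and connection-center evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Individual tree segmentation (ITS) partitions a forest point cloud from
airborne or UAV laser scanning into per-tree subsets, from which tree
counts, positions and heights follow. Canopy-height-model (CHM) watershed
methods are fast but under-segment dense stands: neighboring crowns that
touch in the CHM are fused into one object. `canopycce` refines each
watershed object with a graph clustering on the 3-D points, so fused
crowns can be separated without giving up the watershed's speed.

The pipeline is:

1. **Ground and terrain.** Ground flags are taken from the input when
   present (e.g. a cloth-simulation filter upstream); otherwise a
   minimum-grid classifier flags points within 0.2 m of a TIN surface
   through the per-cell lowest points. The DTM is a linear TIN
   interpolation of the ground points, and heights are normalized as
   `z - DTM(x, y)` (negative residuals clamped to 0).
2. **Pit-free CHM.** The normalized cloud is sliced at 0, 2, 5, 10 and
   15 m; each slice's per-cell highest points are TIN-interpolated into a
   partial CHM, and the final CHM is the cell-wise maximum of the partial
   CHMs together with each cell's own highest point. Layered maxima remove
   "pits" — spuriously low cells inside crowns caused by deep canopy
   returns — which otherwise seed false watershed boundaries.
3. **Watershed.** Tree-top seeds are local maxima in a `(2*ext+1)^2`
   window (`ext` = 2 px); regions flood from the seeds by descending
   height over 8-connected pixels above a 2 m background cutoff. An object
   whose drop between its highest point and its highest contact pixel with
   a neighbor is below `tolerance` (1 m) merges into its highest neighbor.
4. **Per-segment refinement (CCE).** Each segment's points are reduced
   ~10x to weighted super-points by flat-kernel mean shift, then clustered
   by *connection-center evolution*: build the weighted distance
   `d_ij = n_i n_j sqrt(dx^2 + dy^2 + Vr dz^2)`, convert to a Gaussian
   similarity `exp(-d^2 / sigma^2)`, normalize symmetrically by degrees,
   and raise the matrix to increasing powers `k = 1, 2, 4, ...`. At order
   k, points whose diagonal entry dominates their row are cluster centers;
   every point joins the center with the highest relative connectivity
   `S_k[c, j] / S_k[c, c]`. Small k sees every point as a center; large k
   leaves a single center (the leading-eigenvector argmax), so the sweep
   traverses segmentations from micro to macro.
5. **Scale selection.** A sweep result is a candidate when every cluster
   looks like a tree in all three coordinate-plane projections: crown
   widths within a factor 3 of each other, and the highest point farther
   than 1/8 crown width from either crown edge in both x–z and y–z. The
   cluster count backed by the most candidate scales wins (ties to fewer
   clusters), the normalized cut breaks ties within the winning count, and
   a segment with no candidate stays whole.
6. **Post-processing.** Tree tops are per-label height maxima. In
   plantation-like stands, two tops closer than the plot's mean crown
   diameter with a height difference under 10 m merge into one tree —
   repairing the double detections that trunk bifurcation produces.
7. **Evaluation.** Detected and reference trees match one-to-one from the
   tallest detection downward; candidates lie within 5 m horizontally and
   20 % relative height, the smallest height difference wins, and a better
   candidate can displace a previous match (stable re-assignment). From
   TP/FP/FN follow the extraction, matching, commission and omission rates
   and the F-score; height accuracy is reported as R² and RMSE over the
   matched pairs.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cce.vr` | 1/6 | — | Down-weights vertical distance in `d_ij`; compensates occlusion-thinned lower crowns, discourages vertical splits. |
| `cce.sigma` | 30 | weighted m | Gaussian kernel scale of the similarity. Detection metrics are insensitive over a wide range because the center rule is scale-free. |
| `watershed.tolerance` | 1 | m | Minimum seed-to-contact drop separating two objects. |
| `watershed.ext` | 2 | px | Seed-detection window radius; larger smooths out small apices. |
| `watershed.min_height` | 2 | m | Background cutoff; matches the first pit-free slice. |
| `raster.resolution` | auto | m | 0.1 m when canopy sampling density ≥ 100 pts/m², else 0.2 m. |
| `voxel.bandwidth` | auto | m | Mean-shift kernel radius; 0.3/0.6 m by the same density rule, then adapted (below). |
| `scale.edge_fraction` | 1/8 | — | Top-to-edge minimum distance as a crown-width fraction; smaller values over-segment, larger ones under-segment. |
| `merge.height_gap_max` | 10 | m | Height-difference gate of the plantation merge. |
| `match.max_xy_dist`, `match.max_rel_height_diff` | 5 m, 0.2 | | Matching gates; the benchmark protocol they mirror does not print values, so they are explicit configuration here. |

## Numerical choices

* **TIN interpolation** is an own C++ Bowyer–Watson triangulation with
  walk-based point location. Near-degenerate predicates (cocircular
  lattice points from per-cell maxima) are resolved with a relative
  tolerance; any triangulation of cocircular points yields the same linear
  interpolant. Above the 2 m slice, triangles with an edge longer than 3
  cell sizes are dropped so interpolation cannot bridge distinct crowns.
* **Matrix powers** use repeated squaring with symmetrization and a
  rescale by the matrix maximum after each squaring: the normalized
  similarity has spectral radius ≤ 1, so unscaled powers underflow, while
  the center and assignment rules are invariant to positive scaling.
  The sweep stops once a single cluster persists for two consecutive
  scales, or at `k = 2^20`.
* **Voxel-weight underflow.** The weighted distance multiplies by
  `n_i n_j`, so voxel weights far above ~10 push cross-similarities below
  double-precision underflow at `sigma = 30` — the graph disconnects and
  can never merge to one cluster. The pipeline therefore adapts each
  segment's mean-shift bandwidth until the point-to-voxel reduction lands
  in the published ~10x operating band [5, 20]. A `cce.weight_mode =
  "none"` switch drops the weight product for sensitivity checks.
* **Determinism.** Watershed floods pop the globally highest frontier
  pixel with (row, col) tie-breaks; plateau seeds keep the first pixel in
  row-major order; center-rule ties declare the lower index a center;
  merge processes the weakest object first. Identical input and
  configuration reproduce identical labels bit-for-bit.
* **Half-open cells.** A point on a cell boundary belongs to the cell
  whose half-open interval `[x0, x0 + cs)` contains it.

## Design choices where the method description is open

* *"The one with the maximum number of the candidates"* is read as: the
  cluster count attained by the most candidate scales across the k-sweep
  (mode over scales), with the normalized cut choosing within the winning
  group — this uses both stated mechanisms and is recorded as a reading,
  not as the original authors' intent.
* Shape constraints evaluate **original member points**, not super-points;
  extremes from the full point set are sharper.
* The merge rule's *"elevation of these two trees is less than 10 m"* is
  implemented as a height **difference** below 10 m: the literal absolute
  reading contradicts stands whose mean heights exceed 13 m.
* When no scale passes the shape tests the watershed segment is kept whole
  — conservative, never fabricating splits.

## What the synthetic generator emulates — and what it does not

`generate_forest()` builds a sloped, gently undulating terrain, places
stems on a jittered grid honoring a minimum spacing, and samples cone or
ellipsoid crowns **volumetrically** (depth density proportional to slice
area, radius uniform over each slice disk) with exponential occlusion
thinning below the apex; each apex point is always retained, so detection
truth is well defined. Defaults emulate a mid-density conifer ULS plot:
30 x 30 m, 0.05 stems/m², heights 13–25 m, 300 pts/m² nominal crown
sampling. `generate_bifurcated_tree()` puts two apices 1.2 m apart on one
reference tree — the trunk-bifurcation pattern that causes double
detections.

Not emulated: multi-return waveform physics, understorey vegetation,
species-specific crown asymmetry, wind-blown crown interpenetration, and
registration noise. Passing tests on these fixtures therefore demonstrate
the algorithmic contracts (stage correctness, conservation, determinism,
recovery under clean geometry), not field-grade accuracy on natural
forests; on real data the watershed/CCE balance is governed by the same
parameters but accuracy must be validated against field reference.

## Problem sizes used by the test-suite

Unit fixtures use grids up to 30 x 30 cells and segments of a few hundred
points; oracle equivalences run 50–100 randomized instances with n ≤ 15
(clustering) and 30 x 30 CHMs (watershed). The end-to-end check runs the
default 30 x 30 m stand (~55k points, ~45 trees, about 10 s) — small
enough to iterate on, large enough that every stage operates in its
intended regime.

## Known limitations

* LAZ input is not decoded; decompress to LAS first. LAS output is
  version 1.2, point format 0.
* TIFF rasters are written as plain float32 TIFF with an ESRI world file,
  not full GeoTIFF tags; ESRI ASCII grids are the lossless text route.
* The tri-planar shape tests assume roughly convex, single-apex crowns;
  strongly irregular broadleaf canopies can defeat them (kept-whole
  fallback applies).
* Matrix powers are dense: segments are capped by the voxel reduction, and
  very large contiguous canopies fall back to coarser super-points rather
  than out-of-core algebra.
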