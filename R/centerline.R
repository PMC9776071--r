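#' Build a traversal cost volume from a bright-lumen channel
#'
#' Costs are the reciprocal of the floored min-max normalized intensity,
#' `1 / (eps + I_norm)`, so bright (lumen) voxels are cheap to traverse and
#' every cost is bounded by `1 / eps`.
#'
#' With `medialness = TRUE` the normalized intensity is additionally
#' weighted by a saturating distance-to-boundary (medialness) factor
#' computed from the thresholded bright region, which pulls least-cost
#' paths onto the vessel axis instead of letting them cut corners through
#' a uniformly bright lumen.
#'
#' @param stack A `contrast_stack`.
#' @param lumen_channel Channel with flow-related enhancement (default TOF).
#' @param eps Floor of the normalized intensity (default 0.05).
#' @param medialness Weight intensity by centrality (default FALSE).
#' @param medial_scale Saturation scale (mm) of the medialness factor.
#' @param sigma Gaussian pre-smoothing SD in voxels (0 disables); smoothing
#'   stabilizes the near-tied in-lumen costs against acquisition noise.
#' @return A `cost_volume` with fields `costs`, `spacing`, `origin`.
#' @export
build_cost_volume <- function(stack, lumen_channel = "TOF", eps = 0.05,
                              medialness = FALSE, medial_scale = 1,
                              sigma = 0) {
  stopifnot(inherits(stack, "contrast_stack"))
  if (!lumen_channel %in% names(stack$channels))
    stop("no channel named '", lumen_channel, "'")
  img <- stack$channels[[lumen_channel]]
  if (sigma > 0) img <- gauss_blur3d(img, sigma)
  rng <- range(img)
  if (diff(rng) < 1e-12)
    stop("constant-intensity channel: cost normalization degenerate")
  inorm <- (img - rng[1]) / diff(rng)
  if (medialness) {
    bright <- inorm >= 0.5
    edt <- distance_transform(!bright, stack$spacing)  # depth inside lumen
    inorm <- inorm * edt / (edt + medial_scale)
  }
  structure(list(costs = 1 / (eps + inorm), spacing = stack$spacing,
                 origin = stack$origin, eps = eps),
            class = "cost_volume")
}

# run single-source Dijkstra, returning dist/pred on the flattened grid
dijkstra_tree <- function(cost, seed) {
  dims <- dim(cost$costs)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3)
  if (any(seed < 0) || any(seed > dims - 1)) stop("seed outside the grid")
  lin0 <- seed[1] + dims[1] * (seed[2] + dims[2] * seed[3])  # 0-based
  grid_dijkstra_cpp(as.numeric(cost$costs), dims, cost$spacing, lin0)
}

# backtrack a path (matrix of 0-based voxel triplets, source..target)
backtrack_path <- function(tree, dims, target) {
  lin <- target[1] + dims[1] * (target[2] + dims[2] * target[3])
  if (!is.finite(tree$dist[lin + 1]))
    stop("no finite-cost path reaches the target seed")
  idx <- integer(0)
  cur <- lin
  repeat {
    idx <- c(cur, idx)
    p <- tree$pred[cur + 1]
    if (p < 0) break
    cur <- p
  }
  cbind(idx %% dims[1],
        (idx %/% dims[1]) %% dims[2],
        idx %/% (dims[1] * dims[2]))
}

centerline_from_voxels <- function(vox, cost, branch_id, total_cost) {
  pts <- voxel_to_world(vox, cost$spacing, cost$origin)
  structure(list(points = pts, voxels = vox,
                 arclength = polyline_arclength(pts),
                 branch_id = branch_id, total_cost = total_cost),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("Centerline %s: %d points, %.1f mm, total cost %.3g\n",
              x$branch_id, nrow(x$points), max(x$arclength), x$total_cost))
  invisible(x)
}

#' Least-cost path between two seed voxels
#'
#' Dijkstra's algorithm on the 26-connected voxel grid; the weight of an
#' edge is the mean of its endpoint costs times the Euclidean (metric) step
#' length. Ties are broken lexicographically on the voxel linear index, so
#' the result is deterministic.
#'
#' @param cost A `cost_volume`.
#' @param seed_a,seed_b 0-based voxel index triplets.
#' @return A `centerline` ordered from `seed_a` to `seed_b`; `total_cost`
#'   carries the minimum path cost.
#' @export
least_cost_path <- function(cost, seed_a, seed_b) {
  dims <- dim(cost$costs)
  tree <- dijkstra_tree(cost, seed_a)
  seed_b <- as.integer(seed_b)
  vox <- backtrack_path(tree, dims, seed_b)
  lin_b <- seed_b[1] + dims[1] * (seed_b[2] + dims[2] * seed_b[3])
  centerline_from_voxels(vox, cost, "path", tree$dist[lin_b + 1])
}

#' Extract CCA-ICA and CCA-ECA centerlines and the bifurcation apex
#'
#' One single-source Dijkstra run from the CCA seed yields a shortest-path
#' tree; the two branch paths are read off it, so they share a common prefix
#' by construction. The apex is the last common point of the two paths
#' walking from the CCA seed.
#'
#' @param cost A `cost_volume`.
#' @param seed_cca,seed_ica,seed_eca 0-based voxel index triplets; must be
#'   distinct.
#' @return List `ica` (CCA-ICA `centerline`), `eca` (CCA-ECA), `apex`
#'   (world mm), `apex_voxel`.
#' @export
extract_bifurcation_centerlines <- function(cost, seed_cca, seed_ica,
                                            seed_eca) {
  seeds <- list(cca = as.integer(seed_cca), ica = as.integer(seed_ica),
                eca = as.integer(seed_eca))
  if (identical(seeds$ica, seeds$eca) || identical(seeds$cca, seeds$ica) ||
      identical(seeds$cca, seeds$eca))
    stop("the three seeds must be distinct voxels")
  dims <- dim(cost$costs)
  tree <- dijkstra_tree(cost, seeds$cca)
  vox_i <- backtrack_path(tree, dims, seeds$ica)
  vox_e <- backtrack_path(tree, dims, seeds$eca)
  n_common <- 0L
  n_max <- min(nrow(vox_i), nrow(vox_e))
  while (n_common < n_max &&
         all(vox_i[n_common + 1, ] == vox_e[n_common + 1, ])) {
    n_common <- n_common + 1L
  }
  if (n_common == 0L)
    stop("paths share no points; seeds are likely misplaced")
  apex_vox <- vox_i[n_common, ]
  lin <- function(v) v[1] + dims[1] * (v[2] + dims[2] * v[3]) + 1
  list(
    ica = centerline_from_voxels(vox_i, cost, "CCA-ICA",
                                 tree$dist[lin(seeds$ica)]),
    eca = centerline_from_voxels(vox_e, cost, "CCA-ECA",
                                 tree$dist[lin(seeds$eca)]),
    apex = as.numeric(voxel_to_world(matrix(apex_vox, 1), cost$spacing,
                                     cost$origin)),
    apex_voxel = apex_vox
  )
}

#' Moving-average smoothing of a centerline
#'
#' Optional sub-voxel smoothing: each coordinate is smoothed with a centred
#' moving average; endpoints are preserved by edge shrinkage.
#'
#' @param cl A `centerline`.
#' @param window Window size in points (odd; 1 = no smoothing).
#' @return A smoothed `centerline` (same number of points).
#' @export
smooth_centerline <- function(cl, window = 5) {
  pts <- apply(cl$points, 2, moving_average, window = window)
  structure(list(points = pts, voxels = cl$voxels,
                 arclength = polyline_arclength(pts),
                 branch_id = cl$branch_id, total_cost = cl$total_cost),
            class = "centerline")
}

#' Export a centerline as CSV
#'
#' @param cl A `centerline`.
#' @param path Output file.
#' @export
write_centerline <- function(cl, path) {
  df <- data.frame(arclength_mm = cl$arclength, x_mm = cl$points[, 1],
                   y_mm = cl$points[, 2], z_mm = cl$points[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
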