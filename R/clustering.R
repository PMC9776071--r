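#' Extract normalized wall-band intensity features
#'
#' Collects the multi-contrast intensity vector of every voxel in the wall
#' band (between the lumen and the outer wall) and z-scores each channel
#' over the band.
#'
#' @param stack A `contrast_stack`.
#' @param wall_mask Logical 3D array on the stack grid (TRUE = wall band),
#'   e.g. from ground-truth labels or from per-slice contour pairs via
#'   [contours_to_masks()].
#' @return A `feature_table`: `idx` (linear voxel indices), `features`
#'   (z-scored matrix voxels x channels), `center`/`scale` (per-channel
#'   normalization stats), `channels`.
#' @export
extract_wall_features <- function(stack, wall_mask) {
  stopifnot(identical(dim(wall_mask), dim(stack$channels[[1]])))
  idx <- which(wall_mask)
  if (!length(idx)) stop("empty wall band: no voxels between the contours")
  X <- vapply(stack$channels, function(ch) ch[idx], numeric(length(idx)))
  X <- matrix(X, nrow = length(idx),
              dimnames = list(NULL, names(stack$channels)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xn <- scale(X, center = ctr, scale = scl)
  attr(Xn, "scaled:center") <- NULL
  attr(Xn, "scaled:scale") <- NULL
  structure(list(idx = idx, features = Xn, center = ctr, scale = scl,
                 channels = names(stack$channels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d wall-band voxels x %d channels (%s)\n",
              nrow(x$features), length(x$channels),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

# squared Euclidean distances rows of X to rows of C
dist2_to_centroids <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, `+`) - 2 * X %*% t(C)
}

# k-means++ initial centroids (rows of X)
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = p)
    }
    centers[j + 1, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

lloyd_once <- function(X, k, max_iter = 100, tol = 1e-8) {
  centers <- kmeanspp_init(X, k)
  inertia_prev <- Inf
  assign <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
    # Lloyd's iterations can only decrease the objective
    stopifnot(inertia <= inertia_prev + 1e-8 * max(1, inertia_prev))
    for (j in seq_len(k)) {
      rows <- assign == j
      if (!any(rows)) {
        # re-seed an empty cluster at the farthest point
        far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
        centers[j, ] <- X[far, ]
      } else {
        centers[j, ] <- colMeans(X[rows, , drop = FALSE])
      }
    }
    if (inertia_prev - inertia <= tol * max(1, inertia)) {
      inertia_prev <- inertia
      break
    }
    inertia_prev <- inertia
  }
  d2 <- dist2_to_centroids(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  list(assignments = assign, centroids = centers, inertia = inertia)
}

#' K-means clustering of wall-band feature vectors
#'
#' Lloyd's algorithm with k-means++ seeding, keeping the best of `n_init`
#' restarts by inertia. Deterministic for a fixed seed; empty clusters are
#' re-seeded at the farthest point from its centroid.
#'
#' @param features A `feature_table` (or plain numeric matrix).
#' @param k Number of clusters, `>= 2`. Default 4 (arterial wall, lipid,
#'   calcification, mixed).
#' @param seed RNG seed (default 17).
#' @param n_init Number of restarts (default 10).
#' @return A `cluster_result`: `assignments`, `centroids`, `inertia`.
#' @export
kmeans_cluster <- function(features, k = 4, seed = 17, n_init = 10) {
  X <- if (inherits(features, "feature_table")) features$features else
    as.matrix(features)
  if (k < 2) stop("k must be >= 2")
  if (nrow(X) < k) stop("fewer rows than clusters")
  best <- with_seed(seed, {
    res <- NULL
    for (i in seq_len(n_init)) {
      cand <- lloyd_once(X, k)
      if (is.null(res) || cand$inertia < res$inertia) res <- cand
    }
    res
  })
  structure(c(best, list(k = k, idx = if (inherits(features, "feature_table"))
    features$idx else NULL)),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means result: k = %d, n = %d, inertia = %.4g\n",
              x$k, length(x$assignments), x$inertia))
  invisible(x)
}

#' Map clusters to named tissues and relabel the wall band
#'
#' Each centroid is assigned the tissue whose expected signature vector
#' (z-scored with the feature-table statistics) is nearest: calcification is
#' hypointense on all channels, lipid hyperintense on T1W/PDW and
#' hypointense on T2W, remaining clusters map to arterial wall tissue.
#' Surplus clusters merge into the arterial class. A tissue with no claiming
#' centroid is reported via a message, not an error.
#'
#' @param result A `cluster_result` carrying voxel indices.
#' @param features The `feature_table` used for clustering (provides the
#'   normalization statistics).
#' @param labels A `label_volume` to relabel (only wall-band voxels change).
#' @param signatures Raw-intensity signature matrix (classes x channels),
#'   see [default_signatures()].
#' @param classes Candidate classes a centroid may claim. Adding
#'   `"background"` lets dark voxels erroneously included in the band (e.g.
#'   by an over-deep outer-wall trace) be recognized instead of being forced
#'   into calcification, whose signature they resemble.
#' @return A new `label_volume` with wall-band voxels set to the assigned
#'   tissue classes; attribute `cluster_classes` maps cluster id to class.
#' @export
assign_tissue_classes <- function(result, features, labels,
                                  signatures = default_signatures(),
                                  classes = c("wall", "lipid",
                                              "calcification")) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(features, "feature_table"),
            inherits(labels, "label_volume"))
  tissue <- classes
  sig <- signatures[tissue, features$channels, drop = FALSE]
  sig_z <- sweep(sweep(sig, 2, features$center), 2, features$scale, `/`)
  d2 <- dist2_to_centroids(result$centroids, sig_z)
  cls <- tissue[max.col(-d2, ties.method = "first")]
  unclaimed <- setdiff(tissue, cls)
  if (length(unclaimed))
    message("no cluster claimed class(es): ",
            paste(unclaimed, collapse = ", "))
  new_labels <- labels$labels
  new_labels[features$idx] <- tissue_codes[cls[result$assignments]]
  out <- label_volume(new_labels, labels$spacing, labels$origin)
  attr(out, "cluster_classes") <- cls
  out
}
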