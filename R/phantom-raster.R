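#' Construct a label volume container
#'
#' @param labels 3D integer array with classes from [tissue_codes].
#' @param spacing Length-3 voxel spacing (mm).
#' @param origin Length-3 world coordinate (mm) of voxel (0,0,0) centre.
#' @return A `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, all(spacing > 0))
  storage.mode(labels) <- "integer"
  if (!all(labels %in% tissue_codes))
    stop("labels outside the closed class set {0..4}")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume", paste(dim(x$labels), collapse = " x "),
      "at", paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  tab <- table(factor(x$labels, levels = tissue_codes,
                      labels = names(tissue_codes)))
  print(tab)
  invisible(x)
}

# default grid: axis-aligned, enclosing all outer surfaces plus a margin
default_grid <- function(geometry, spacing, margin = 1.5) {
  pts <- do.call(rbind, lapply(geometry$branches, function(b) b$points))
  rmax <- max(vapply(geometry$branches, function(b) max(b$r_outer), 0))
  lo <- apply(pts, 2, min) - rmax - margin
  hi <- apply(pts, 2, max) + rmax + margin
  spacing <- rep(spacing, length.out = 3)
  # align voxel centres with integer multiples of the spacing so that the
  # world origin (the CCA axis) is a voxel centre, not a cell face
  lo <- spacing * floor(lo / spacing)
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(spacing = spacing, origin = lo, dims = dims)
}

# mark voxels within swept spheres along centres (n x 3) with radii r (n)
sweep_tube_mask <- function(mask, centers, radii, spacing, origin) {
  dims <- dim(mask)
  ax <- origin[1] + spacing[1] * (seq_len(dims[1]) - 1)
  ay <- origin[2] + spacing[2] * (seq_len(dims[2]) - 1)
  az <- origin[3] + spacing[3] * (seq_len(dims[3]) - 1)
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]; r <- radii[i]
    ix <- which(abs(ax - p[1]) <= r)
    iy <- which(abs(ay - p[2]) <= r)
    iz <- which(abs(az - p[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - p[1])^2
    dy2 <- (ay[iy] - p[2])^2
    dz2 <- (az[iz] - p[3])^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    mask[ix, iy, iz] <- mask[ix, iy, iz, drop = FALSE] | sub
  }
  mask
}

# 0-based voxel triplets whose centres lie inside an ellipsoid spec
ellipsoid_voxels <- function(ell, spacing, origin, dims) {
  rmax <- max(ell$semi_axes)
  lo <- pmax(floor((ell$center - rmax - origin) / spacing), 0)
  hi <- pmin(ceiling((ell$center + rmax - origin) / spacing), dims - 1)
  if (any(hi < lo)) return(matrix(integer(0), ncol = 3))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  idx <- as.matrix(expand.grid(gx, gy, gz))
  pts <- voxel_to_world(idx, spacing, origin)
  rel <- sweep(pts, 2, ell$center)
  if (!is.null(ell$axes)) rel <- rel %*% ell$axes
  q <- rowSums(sweep(rel, 2, ell$semi_axes, `/`)^2)
  idx[q <= 1, , drop = FALSE]
}

#' Rasterize geometry and plaque components into a label volume
#'
#' Voxels are classified at their centres: lumen inside the (possibly
#' stenosed) lumen tube, wall between lumen and outer surfaces, and lipid or
#' calcification where an inclusion ellipsoid overrides the wall. Tubes are
#' swept as unions of spheres along finely sampled axes; with the default
#' axis step the scalloping depth is far below the voxel size.
#'
#' @param geometry A `vessel_geometry`.
#' @param plaque A [plaque_spec()] (may be empty).
#' @param grid Either a single spacing (mm) or a list with `spacing`,
#'   `origin`, `dims`.
#' @return A `label_volume`; attribute `class_counts` holds ground-truth
#'   voxel counts per class.
#' @export
rasterize_labels <- function(geometry, plaque = plaque_spec(), grid = 0.5) {
  if (!is.list(grid)) grid <- default_grid(geometry, spacing = grid)
  spacing <- grid$spacing; origin <- grid$origin; dims <- grid$dims

  pts <- do.call(rbind, lapply(geometry$branches, function(b) b$points))
  lo_need <- apply(pts, 2, min); hi_need <- apply(pts, 2, max)
  hi_have <- origin + spacing * (dims - 1)
  if (any(origin > lo_need) || any(hi_have < hi_need))
    stop("grid does not enclose the geometry bounding box")

  lumen <- array(FALSE, dims)
  outer_m <- array(FALSE, dims)
  for (b in geometry$branches) {
    lumen <- sweep_tube_mask(lumen, b$centers, b$r_lumen, spacing, origin)
    outer_m <- sweep_tube_mask(outer_m, b$points, b$r_outer, spacing, origin)
  }
  labels <- array(tissue_codes[["background"]], dims)
  labels[outer_m] <- tissue_codes[["wall"]]
  labels[lumen] <- tissue_codes[["lumen"]]

  add_inclusions <- function(labels, regions, code) {
    for (ell in regions) {
      idx <- ellipsoid_voxels(ell, spacing, origin, dims)
      if (!nrow(idx)) next
      lin <- voxel_linear_index(idx, dims)
      cur <- labels[lin]
      # same-class ellipsoids may overlap (their union forms the region);
      # anything else means the inclusion escapes the wall band
      if (any(!cur %in% c(tissue_codes[["wall"]], code)))
        stop("inclusion region '", ell$name %||% "unnamed",
             "' escapes the wall band (overlaps ",
             paste(unique(names(tissue_codes)[match(
               cur[cur != tissue_codes[["wall"]]], tissue_codes)]),
               collapse = ", "), ")")
      labels[lin] <- code
    }
    labels
  }
  labels <- add_inclusions(labels, plaque$lipid, tissue_codes[["lipid"]])
  labels <- add_inclusions(labels, plaque$calcification,
                           tissue_codes[["calcification"]])

  lv <- label_volume(labels, spacing, origin)
  counts <- vapply(tissue_codes, function(code) sum(labels == code), 0L)
  attr(lv, "class_counts") <- counts
  lv
}

#' Default per-class multi-contrast intensity signatures
#'
#' Relative intensities (arbitrary units, roughly 0-1) per contrast channel
#' following standard multi-contrast plaque MRI conventions: flowing blood is
#' the brightest class on TOF (flow-related enhancement), lipid is
#' hyperintense on T1W/PDW and hypointense on T2W, calcification is
#' hypointense on all channels.
#'
#' @return Matrix classes x channels (T1W, T2W, PDW, TOF).
#' @export
default_signatures <- function() {
  sig <- rbind(
    background    = c(0.03, 0.03, 0.03, 0.03),
    lumen         = c(0.30, 0.35, 0.30, 0.95),
    wall          = c(0.55, 0.50, 0.55, 0.30),
    lipid         = c(0.75, 0.25, 0.70, 0.30),
    calcification = c(0.15, 0.15, 0.15, 0.15)
  )
  colnames(sig) <- c("T1W", "T2W", "PDW", "TOF")
  sig
}

#' Construct a multi-contrast image stack container
#'
#' @param channels Named list of 3D arrays sharing a grid.
#' @param spacing,origin Grid metadata (mm).
#' @return A `contrast_stack`.
#' @export
contrast_stack <- function(channels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  stopifnot(all(spacing > 0))
  structure(list(channels = channels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "contrast_stack")
}

#' @export
print.contrast_stack <- function(x, ...) {
  cat("Contrast stack [", paste(names(x$channels), collapse = ", "), "] ",
      paste(dim(x$channels[[1]]), collapse = " x "), " at ",
      paste(signif(x$spacing, 3), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Render multi-contrast images from a label volume
#'
#' Each channel is the per-class signature mean plus additive Gaussian noise,
#' generated channel by channel in a fixed order so a fixed seed gives
#' bit-identical volumes.
#'
#' @param labels A `label_volume`.
#' @param signatures Classes x channels matrix, see [default_signatures()].
#' @param noise_sd Per-channel noise SD (recycled), `>= 0`.
#' @param seed Integer seed for the noise.
#' @return A `contrast_stack` on the label grid.
#' @export
render_contrasts <- function(labels, signatures = default_signatures(),
                             noise_sd = 0.05, seed = 1L) {
  present <- names(tissue_codes)[tissue_codes %in% unique(as.vector(labels$labels))]
  missing_sig <- setdiff(present, rownames(signatures))
  if (length(missing_sig))
    stop("missing intensity signature for class(es): ",
         paste(missing_sig, collapse = ", "))
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  noise_sd <- rep(noise_sd, length.out = ncol(signatures))
  class_row <- match(names(tissue_codes)[match(labels$labels, tissue_codes)],
                     rownames(signatures))
  dims <- dim(labels$labels)
  channels <- with_seed(seed, {
    out <- list()
    for (j in seq_len(ncol(signatures))) {
      ch <- array(signatures[class_row, j], dims)
      if (noise_sd[j] > 0)
        ch <- ch + array(rnorm(prod(dims), sd = noise_sd[j]), dims)
      out[[colnames(signatures)[j]]] <- ch
    }
    out
  })
  contrast_stack(channels, labels$spacing, labels$origin)
}
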