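#' Volume of a tissue component
#'
#' Voxel count times voxel volume.
#'
#' @param labels A `label_volume`.
#' @param tissue Class name (see [tissue_codes]).
#' @return Volume in mm^3.
#' @export
component_volume <- function(labels, tissue) {
  if (!tissue %in% names(tissue_codes)) stop("unknown tissue class: ", tissue)
  sum(labels$labels == tissue_codes[[tissue]]) * prod(labels$spacing)
}

# 6-connected boundary voxels of a class mask (TRUE voxels adjacent to FALSE)
mask_boundary <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb_all <- array(TRUE, d)
  for (ax in 1:3) for (by in c(-1, 1)) {
    sh <- shift(mask, ax, by)
    # faces at the array edge count as boundary
    nb_all <- nb_all & sh
  }
  mask & !nb_all
}

# number of TRUE 6-neighbours per voxel
neighbor_count <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  shift_add <- function(out, ax, by) {
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]], drop = FALSE] +
      mask[src[[1]], src[[2]], src[[3]], drop = FALSE]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- shift_add(out, ax, by)
  out
}

#' Euclidean distance transform of a mask
#'
#' Exact distance (mm) from every voxel centre to the nearest TRUE voxel
#' centre, honouring anisotropic spacing.
#'
#' @param mask Logical 3D array.
#' @param spacing Length-3 spacing (mm).
#' @return Numeric 3D array of distances.
#' @export
distance_transform <- function(mask, spacing) {
  d <- dim(mask)
  out <- grid_edt_cpp(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(out, d)
}

#' Thinnest fibrous cap thickness
#'
#' Minimum Euclidean distance from the lumen boundary to the lipid boundary:
#' a distance transform seeded on lumen-surface voxels is sampled at
#' lipid-surface voxels. Reported in mm. A lipid core touching the lumen
#' (thickness at or below one voxel spacing) is flagged as a cap breach.
#'
#' @param labels A `label_volume`.
#' @return List `thickness_mm` (NA when no lipid present), `absent`,
#'   `breach`, `lumen_point`/`lipid_point` left NULL (positions not tracked).
#' @export
thinnest_fibrous_cap <- function(labels) {
  lipid <- labels$labels == tissue_codes[["lipid"]]
  if (!any(lipid))
    return(list(thickness_mm = NA_real_, absent = TRUE, breach = FALSE))
  lumen <- labels$labels == tissue_codes[["lumen"]]
  if (!any(lumen)) stop("label volume contains no lumen")
  lumen_surf <- mask_boundary(lumen)
  lipid_surf <- mask_boundary(lipid)
  dt <- distance_transform(lumen_surf, labels$spacing)
  thick <- min(dt[lipid_surf])
  list(thickness_mm = thick, absent = FALSE,
       breach = thick <= max(labels$spacing))
}

#' Lumen radius profile along a centerline by ray casting
#'
#' At each centerline sample the lumen boundary is located along rays
#' orthogonal to the local tangent by bisection on the trilinearly
#' interpolated lumen indicator (0.5 level), giving a sub-voxel estimate.
#' Before measuring, each section point is recentred by a few chord-midpoint
#' iterations (the mean of opposite-ray chord midpoints converges
#' geometrically to the centre of a circular section), which removes the
#' radius inflation a voxel-snapped centerline would otherwise cause. The
#' per-section radius is the mean ray length from the recentred point; the
#' profile is smoothed with a short moving average.
#'
#' @param lumen_mask Logical 3D array (TRUE = lumen).
#' @param spacing,origin Grid metadata.
#' @param centerline A `centerline` (or matrix of points).
#' @param n_rays Rays per section (even).
#' @param r_max Maximum search radius (mm).
#' @param smooth_window Moving-average window (samples; 1 disables).
#' @param recenter Chord-midpoint recentring iterations.
#' @return Data frame `arclength_mm`, `radius_mm`.
#' @export
lumen_radius_profile <- function(lumen_mask, spacing, origin, centerline,
                                 n_rays = 32, r_max = 6,
                                 smooth_window = 5, recenter = 3) {
  pts <- if (inherits(centerline, "centerline")) centerline$points else
    as.matrix(centerline)
  tans <- polyline_tangents(pts)
  mask_num <- array(as.numeric(lumen_mask), dim(lumen_mask))
  n <- nrow(pts)
  radius <- rep(NA_real_, n)
  th <- seq(0, 2 * pi, length.out = n_rays + 1)[seq_len(n_rays)]
  coarse <- seq(0, r_max, by = min(spacing) / 2)

  cast_rays <- function(p, dirs) {
    nr <- nrow(dirs)
    nc <- length(coarse)
    # all coarse samples for all rays in one interpolation call
    q <- matrix(p, nr * nc, 3, byrow = TRUE) +
      dirs[rep(seq_len(nr), each = nc), ] * rep(coarse, nr)
    vals <- matrix(trilinear_interp(mask_num, spacing, origin, q), nc, nr)
    first_out <- apply(vals < 0.5, 2, function(z) which(z)[1])
    ok <- !is.na(first_out) & first_out > 1
    lo <- hi <- rep(NA_real_, nr)
    lo[ok] <- coarse[first_out[ok] - 1]
    hi[ok] <- coarse[first_out[ok]]
    if (any(ok)) {
      for (b in 1:25) {  # vectorized bisection across rays
        mid <- (lo[ok] + hi[ok]) / 2
        pm <- matrix(p, sum(ok), 3, byrow = TRUE) +
          dirs[ok, , drop = FALSE] * mid
        inside <- trilinear_interp(mask_num, spacing, origin, pm) >= 0.5
        lo[ok][inside] <- mid[inside]
        hi[ok][!inside] <- mid[!inside]
      }
    }
    (lo + hi) / 2
  }

  for (i in seq_len(n)) {
    t <- tans[i, ]
    ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    e1 <- ref - sum(ref * t) * t
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t[2] * e1[3] - t[3] * e1[2], t[3] * e1[1] - t[1] * e1[3],
            t[1] * e1[2] - t[2] * e1[1])
    p <- pts[i, ]
    if (trilinear_interp(mask_num, spacing, origin, matrix(p, 1)) < 0.5)
      next  # centre not inside the lumen: leave NA
    dirs <- outer(cos(th), e1) + outer(sin(th), e2)
    half <- n_rays / 2
    for (it in seq_len(recenter)) {
      rlen <- cast_rays(p, dirs)
      if (mean(is.na(rlen)) > 0.25) break
      mids <- (rlen[seq_len(half)] - rlen[half + seq_len(half)]) / 2
      ok <- !is.na(mids)
      if (!any(ok)) break
      shift <- colMeans(mids[ok] * dirs[seq_len(half), , drop = FALSE][ok, ,
                                                                 drop = FALSE])
      p_new <- p + shift
      if (trilinear_interp(mask_num, spacing, origin,
                           matrix(p_new, 1)) < 0.5) break
      p <- p_new
    }
    rlen <- cast_rays(p, dirs)
    if (mean(is.na(rlen)) <= 0.25) radius[i] <- mean(rlen, na.rm = TRUE)
  }
  s <- polyline_arclength(pts)
  keep <- !is.na(radius)
  out <- data.frame(arclength_mm = s[keep], radius_mm = radius[keep])
  if (smooth_window > 1 && nrow(out) > 2)
    out$radius_mm <- moving_average(out$radius_mm, smooth_window)
  out
}

#' NASCET stenosis degree from an ICA radius profile
#'
#' `100 * (1 - d_min / d_distal)` where `d_min` is the minimum lumen
#' diameter over the profile and `d_distal` the mean diameter over the last
#' `distal_window` mm, taken as the normal distal reference segment.
#'
#' @param radius_profile Data frame `arclength_mm`, `radius_mm` (see
#'   [lumen_radius_profile()]).
#' @param distal_window Distal reference length (mm), default 5.
#' @return Stenosis degree in percent.
#' @export
nascet_stenosis <- function(radius_profile, distal_window = 5) {
  s <- radius_profile$arclength_mm
  r <- radius_profile$radius_mm
  if (length(s) < 3) stop("radius profile too short")
  d_min <- 2 * min(r)
  s_end <- max(s)
  distal <- r[s >= s_end - distal_window]
  d_distal <- 2 * mean(distal)
  if (d_distal <= 0) stop("distal reference diameter is zero")
  100 * (1 - d_min / d_distal)
}

#' Quantify plaque morphology
#'
#' Component volumes, thinnest fibrous cap and NASCET stenosis degree in a
#' single report.
#'
#' @param labels A `label_volume` (tissue-classified).
#' @param ica_radius_profile Optional data frame for [nascet_stenosis()].
#' @param distal_window Distal reference length (mm).
#' @return A `morphology_report` list with fields `calcification_volume_mm3`,
#'   `lipid_volume_mm3`, `wall_volume_mm3`, `thinnest_cap_mm`, `cap_absent`,
#'   `cap_breach`, `stenosis_percent`.
#' @export
morphology_report <- function(labels, ica_radius_profile = NULL,
                              distal_window = 5) {
  cap <- thinnest_fibrous_cap(labels)
  sten <- if (!is.null(ica_radius_profile))
    nascet_stenosis(ica_radius_profile, distal_window) else NA_real_
  structure(list(
    calcification_volume_mm3 = component_volume(labels, "calcification"),
    lipid_volume_mm3 = component_volume(labels, "lipid"),
    wall_volume_mm3 = component_volume(labels, "wall"),
    thinnest_cap_mm = cap$thickness_mm,
    cap_absent = cap$absent,
    cap_breach = cap$breach,
    stenosis_percent = sten
  ), class = "morphology_report")
}

#' @export
print.morphology_report <- function(x, ...) {
  cat("Plaque morphology\n")
  cat(sprintf("  calcification %.2f mm^3, lipid %.2f mm^3\n",
              x$calcification_volume_mm3, x$lipid_volume_mm3))
  cat(sprintf("  thinnest fibrous cap: %s\n",
              if (x$cap_absent) "absent (no lipid)" else
                sprintf("%.3f mm%s", x$thinnest_cap_mm,
                        if (x$cap_breach) " [cap breach]" else "")))
  if (!is.na(x$stenosis_percent))
    cat(sprintf("  NASCET stenosis: %.1f%%\n", x$stenosis_percent))
  invisible(x)
}
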