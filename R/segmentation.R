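#' Extract one axial slice of a contrast stack
#'
#' @param stack A `contrast_stack`.
#' @param channel Channel name.
#' @param slice_index 0-based z slice index.
#' @return List `image` (2D matrix), `spacing`, `origin` (x, y of pixel
#'   (0,0) centre), `z` (slice world coordinate), `slice_index`.
#' @export
get_slice <- function(stack, channel, slice_index) {
  img <- stack$channels[[channel]][, , slice_index + 1]
  list(image = img, spacing = stack$spacing[1:2], origin = stack$origin[1:2],
       z = stack$origin[3] + stack$spacing[3] * slice_index,
       slice_index = slice_index)
}

new_contour <- function(vertices, slice_index, kind) {
  structure(list(vertices = vertices, slice_index = slice_index,
                 kind = kind),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("%s contour, slice %d: %d vertices, area %.2f mm^2\n",
              x$kind, x$slice_index, nrow(x$vertices),
              abs(polygon_area(x$vertices))))
  invisible(x)
}

# counter-clockwise circle polygon
circle_contour <- function(center, r, slice_index, n_vertices = 64,
                           kind = "lumen") {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  new_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
              slice_index, kind)
}

#' Initialize per-slice lumen contours from a centerline
#'
#' One circle of radius `r0` per slice plane the centerline intersects,
#' centred at the in-plane centerline position. Slices the centerline does
#' not reach are skipped with a warning collected in the result attribute.
#'
#' @param centerline A `centerline`.
#' @param stack A `contrast_stack` providing the slice grid.
#' @param r0 Initial radius (mm), `> 0`.
#' @param n_vertices Polygon vertices per contour.
#' @return List of `contour`s (kind `"lumen"`), one per intersected slice.
#' @export
init_contours_from_centerline <- function(centerline, stack, r0 = 1.2,
                                          n_vertices = 64) {
  if (r0 <= 0) stop("r0 must be positive")
  dz <- stack$spacing[3]
  nz <- dim(stack$channels[[1]])[3]
  out <- list()
  for (iz in 0:(nz - 1)) {
    zw <- stack$origin[3] + dz * iz
    d <- abs(centerline$points[, 3] - zw)
    i <- which.min(d)
    if (d[i] > dz / 2) next
    out[[length(out) + 1]] <- circle_contour(centerline$points[i, 1:2], r0,
                                             iz, n_vertices)
  }
  if (!length(out)) warning("centerline intersects no slice planes")
  out
}

# Gaussian blur of a 2D image (separable, reflected edges), sigma in pixels
gauss_blur2d <- function(img, sigma = 1.2) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_filter <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rev(seq_len(half)), , drop = FALSE], m,
                m[n + 1 - seq_len(half), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[seq_len(n) + j - 1, , drop = FALSE]
    out
  }
  t(pad_filter(t(pad_filter(img))))
}

# gradient-magnitude image and its spatial gradient (for snake forces)
edge_fields <- function(img, spacing, sigma = 1.2) {
  sm <- gauss_blur2d(img, sigma)
  gx <- (rbind(sm[-1, ], sm[nrow(sm), ]) - rbind(sm[1, ], sm[-nrow(sm), ])) /
    (2 * spacing[1])
  gy <- (cbind(sm[, -1], sm[, ncol(sm)]) - cbind(sm[, 1], sm[, -ncol(sm)])) /
    (2 * spacing[2])
  mag <- sqrt(gx^2 + gy^2)
  mx <- (rbind(mag[-1, ], mag[nrow(mag), ]) -
           rbind(mag[1, ], mag[-nrow(mag), ])) / (2 * spacing[1])
  my <- (cbind(mag[, -1], mag[, ncol(mag)]) -
           cbind(mag[, 1], mag[, -ncol(mag)])) / (2 * spacing[2])
  scale <- max(mag, 1e-12)
  list(mag = mag / scale, fx = mx / scale, fy = my / scale)
}

# resample a closed polygon to n equally spaced vertices along its perimeter
resample_closed <- function(v, n = nrow(v)) {
  vc <- rbind(v, v[1, ])
  s <- c(0, cumsum(sqrt(rowSums(diff(vc)^2))))
  if (s[length(s)] < 1e-12) return(v)
  sq <- seq(0, s[length(s)], length.out = n + 1)[1:n]
  cbind(approx(s, vc[, 1], xout = sq)$y, approx(s, vc[, 2], xout = sq)$y)
}

polygon_perimeter <- function(v) {
  vc <- rbind(v, v[1, ])
  sum(sqrt(rowSums(diff(vc)^2)))
}

# TRUE if any two non-adjacent edges of the closed polygon intersect
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a1 <- v
  a2 <- v[c(2:n, 1), ]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    p <- a1[i, ]; r <- a2[i, ] - p
    q1 <- a1[js, , drop = FALSE]
    s2 <- a2[js, , drop = FALSE] - q1
    denom <- r[1] * s2[, 2] - r[2] * s2[, 1]
    dq <- sweep(q1, 2, p)
    t_ <- (dq[, 1] * s2[, 2] - dq[, 2] * s2[, 1]) / denom
    u_ <- (dq[, 1] * r[2] - dq[, 2] * r[1]) / -denom
    hit <- is.finite(t_) & is.finite(u_) &
      t_ > 1e-9 & t_ < 1 - 1e-9 & u_ > 1e-9 & u_ < 1 - 1e-9
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# star-shaped repair: project vertices onto rays from the centroid
star_repair <- function(v) {
  c0 <- colMeans(v)
  th <- atan2(v[, 2] - c0[2], v[, 1] - c0[1])
  r <- sqrt((v[, 1] - c0[1])^2 + (v[, 2] - c0[2])^2)
  o <- order(th)
  cbind(c0[1] + r[o] * cos(th[o]), c0[2] + r[o] * sin(th[o]))
}

#' Snake parameters
#'
#' @param alpha Tension (stretch) weight.
#' @param beta Rigidity (bending) weight.
#' @param kappa Image-force weight (gradient-magnitude ascent).
#' @param pressure Outward balloon pressure weight (0 disables; positive
#'   values let a contour initialized inside the lumen inflate to the edge).
#' @param gamma Step size (mm per iteration per unit force).
#' @param iters Maximum iterations.
#' @param tol Convergence threshold on the maximum vertex move (mm).
#' @param sigma Gaussian pre-smoothing SD (pixels).
#' @return Named list of parameters.
#' @export
snake_params <- function(alpha = 0.4, beta = 0.3, kappa = 1.3,
                         pressure = 0.22, gamma = 0.25, iters = 300,
                         tol = 0.01, sigma = 1.2) {
  list(alpha = alpha, beta = beta, kappa = kappa, pressure = pressure,
       gamma = gamma, iters = iters, tol = tol, sigma = sigma)
}

#' Evolve an active contour on one slice
#'
#' Explicit-Euler snake minimizing tension plus bending internal energy and
#' the negative gradient-magnitude image energy, with an optional outward
#' balloon pressure. Stops when the maximum vertex move drops below
#' `params$tol` (mm) or after `params$iters` iterations. The contour is
#' periodically resampled to equal vertex spacing; a self-intersecting
#' result is repaired by star-shaped resampling around the centroid.
#'
#' @param slice List from [get_slice()] (or `image`/`spacing`/`origin`).
#' @param init A `contour` to initialize from.
#' @param params List from [snake_params()].
#' @return The converged `contour` (same kind and slice as `init`).
#' @export
evolve_active_contour <- function(slice, init, params = snake_params()) {
  img <- slice$image
  spacing <- slice$spacing
  origin <- slice$origin
  ef <- edge_fields(img, spacing, params$sigma)
  v <- init$vertices
  n <- nrow(v)
  step <- params$gamma * min(spacing)
  for (it in seq_len(params$iters)) {
    ip <- c(n, 1:(n - 1)); inx <- c(2:n, 1)
    ipp <- c(n - 1, n, 1:(n - 2)); inn <- c(3:n, 1, 2)
    tension <- v[ip, ] + v[inx, ] - 2 * v
    bend <- -(v[ipp, ] - 4 * v[ip, ] + 6 * v - 4 * v[inx, ] + v[inn, ])
    # grid coordinates for force sampling
    fx <- bilinear_interp(ef$fx, spacing, origin, v)
    fy <- bilinear_interp(ef$fy, spacing, origin, v)
    fimg <- cbind(fx, fy)
    # outward normal of a CCW polygon
    tvec <- v[inx, ] - v[ip, ]
    nrm <- cbind(tvec[, 2], -tvec[, 1])
    nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
    if (polygon_area(v) < 0) nrm <- -nrm
    move <- step * (params$alpha * tension + params$beta * bend +
                    params$kappa * fimg + params$pressure * nrm)
    v <- v + move
    if (it %% 10 == 0) v <- resample_closed(v, n)
    if (max(abs(move)) < params$tol) break
  }
  v <- resample_closed(v, n)
  if (polygon_self_intersects(v)) v <- star_repair(v)
  if (polygon_area(v) < 0) v <- v[rev(seq_len(n)), ]  # keep CCW
  if (abs(polygon_area(v)) < prod(spacing))
    stop("contour collapsed below one voxel area; try a larger r0")
  new_contour(v, init$slice_index, init$kind)
}

# polygon radius at given angles around a centre (star-shaped assumption)
polygon_radius_at <- function(v, center, angles) {
  th <- atan2(v[, 2] - center[2], v[, 1] - center[1])
  r <- sqrt((v[, 1] - center[1])^2 + (v[, 2] - center[2])^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # periodic interpolation
  th2 <- c(th - 2 * pi, th, th + 2 * pi)
  r2 <- rep(r, 3)
  angles <- ((angles + pi) %% (2 * pi)) - pi
  approx(th2, r2, xout = angles)$y
}

#' Build a polar intensity/gradient map around a lumen contour
#'
#' Rays from the lumen centroid; radial samples start just outside the lumen
#' boundary at each angle and extend `r_max_offset` mm beyond it. The
#' outward radial gradient is a central difference of the interpolated
#' intensities along each ray.
#'
#' @param slice List from [get_slice()].
#' @param lumen Lumen `contour`.
#' @param n_theta,n_r Angular and radial sample counts.
#' @param r_max_offset Radial search depth beyond the lumen boundary (mm).
#' @param r_inset Start offset beyond the lumen boundary (mm).
#' @return A `polar_map`: `angles`, `radii` (n_theta x n_r, mm from the
#'   centroid), `intensity`, `gradient`, `center`.
#' @export
build_polar_map <- function(slice, lumen, n_theta = 72, n_r = 40,
                            r_max_offset = 3, r_inset = 0.15) {
  stopifnot(n_theta >= 36, n_r >= 4, r_max_offset > 0)
  center <- polygon_centroid(lumen$vertices)
  angles <- seq(0, 2 * pi, length.out = n_theta + 1)[seq_len(n_theta)]
  rho <- polygon_radius_at(lumen$vertices, center, angles)
  radii <- outer(rho + r_inset, seq(0, r_max_offset, length.out = n_r), `+`)
  px <- center[1] + radii * cos(angles)
  py <- center[2] + radii * sin(angles)
  sm <- gauss_blur2d(slice$image, 1.0)
  ii <- bilinear_interp(sm, slice$spacing, slice$origin,
                        cbind(as.vector(px), as.vector(py)))
  intensity <- matrix(ii, n_theta, n_r)
  dr <- radii[, 2] - radii[, 1]
  grad <- intensity
  grad[, 2:(n_r - 1)] <- (intensity[, 3:n_r] - intensity[, 1:(n_r - 2)]) /
    (2 * dr)
  grad[, 1] <- (intensity[, 2] - intensity[, 1]) / dr
  grad[, n_r] <- (intensity[, n_r] - intensity[, n_r - 1]) / dr
  structure(list(angles = angles, radii = radii, intensity = intensity,
                 gradient = grad, center = center),
            class = "polar_map")
}

#' Minimal-cost cyclic path over a polar cost matrix
#'
#' Chooses one radial sample per ray minimizing the node costs plus a
#' smoothness penalty `lambda * |delta index|` between consecutive rays
#' (cyclically), with the step restricted to `|delta| <= max_step` samples.
#' Solved exactly by dynamic programming, closing the cycle by fixing the
#' first ray's radius over all choices and keeping the best.
#'
#' @param cost n_theta x n_r node cost matrix.
#' @param lambda Smoothness weight per index step.
#' @param max_step Maximum radial index change per ray step.
#' @return List `path` (radial index per ray), `cost` (total).
#' @export
cyclic_polar_path <- function(cost, lambda = 0.5, max_step = 2) {
  nt <- nrow(cost); nr <- ncol(cost)
  shifts <- -max_step:max_step
  best_cost <- Inf
  best_path <- NULL
  for (j0 in seq_len(nr)) {
    dp <- rep(Inf, nr)
    dp[j0] <- cost[1, j0]
    ptr <- matrix(0L, nt, nr)
    for (t in 2:nt) {
      cand <- matrix(Inf, nr, length(shifts))
      for (si in seq_along(shifts)) {
        d <- shifts[si]
        src <- seq_len(nr) - d
        ok <- src >= 1 & src <= nr
        cand[ok, si] <- dp[src[ok]] + lambda * abs(d)
      }
      pick <- max.col(-cand, ties.method = "first")
      dp <- cand[cbind(seq_len(nr), pick)] + cost[t, ]
      ptr[t, ] <- seq_len(nr) - shifts[pick]
    }
    # closure back to j0
    dclose <- abs(seq_len(nr) - j0)
    total <- dp + ifelse(dclose <= max_step, lambda * dclose, Inf)
    jend <- which.min(total)
    if (total[jend] < best_cost) {
      best_cost <- total[jend]
      path <- integer(nt)
      path[nt] <- jend
      for (t in nt:2) path[t - 1] <- ptr[t, path[t]]
      best_path <- path
    }
  }
  list(path = best_path, cost = best_cost)
}

#' Trace the outer wall by circle-model minimal-path tracking
#'
#' Builds a polar map around the lumen and finds the minimal-cost cyclic
#' radial path. With `edge = "falling"` (default) the node cost is the
#' outward radial gradient, so radii where the intensity drops most steeply
#' going outwards (wall-to-background boundary on a bright-wall channel) are
#' cheapest; `"rising"` negates it. Large `lambda` drives the solution
#' towards a constant-radius circle.
#'
#' @param slice List from [get_slice()].
#' @param lumen Lumen `contour`.
#' @param lambda Smoothness weight; `n_theta`, `n_r`, `r_max_offset` as in
#'   [build_polar_map()].
#' @param edge `"falling"` or `"rising"` target edge polarity.
#' @inheritParams build_polar_map
#' @return Outer-wall `contour` enclosing the lumen; attribute
#'   `at_bound_frac` gives the fraction of rays whose radius hit the search
#'   bound (warned about above 20 percent).
#' @export
trace_outer_wall <- function(slice, lumen, lambda = 0.5, n_theta = 72,
                             n_r = 40, r_max_offset = 3,
                             edge = c("falling", "rising")) {
  edge <- match.arg(edge)
  pm <- build_polar_map(slice, lumen, n_theta, n_r, r_max_offset)
  node_cost <- if (edge == "falling") pm$gradient else -pm$gradient
  # scale lambda by the cost spread so smoothness is unit-comparable
  lam <- lambda * max(diff(range(node_cost)), 1e-12) / n_r
  sol <- cyclic_polar_path(node_cost, lambda = lam, max_step = 2)
  at_bound <- mean(sol$path == ncol(node_cost))
  if (at_bound > 0.2)
    warning(sprintf("outer wall hit the search bound on %.0f%% of rays; ",
                    100 * at_bound),
            "wall may lie outside r_max_offset")
  r <- pm$radii[cbind(seq_len(n_theta), sol$path)]
  v <- cbind(pm$center[1] + r * cos(pm$angles),
             pm$center[2] + r * sin(pm$angles))
  out <- new_contour(v, lumen$slice_index, "outer_wall")
  attr(out, "at_bound_frac") <- at_bound
  attr(out, "path_cost") <- sol$cost
  out
}

#' Export contours as a per-slice CSV
#'
#' @param contours List of `contour`s.
#' @param path Output file.
#' @export
write_contours <- function(contours, path) {
  rows <- lapply(contours, function(ct)
    data.frame(slice = ct$slice_index,
               vertex = seq_len(nrow(ct$vertices)) - 1L,
               x_mm = ct$vertices[, 1], y_mm = ct$vertices[, 2],
               kind = ct$kind))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
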