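# Small shared numerical helpers. All lengths are mm, times s, stresses Pa
# (kPa only where a function documents it), mmHg accepted at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily seeded RNG
#'
#' Seeds R's RNG, runs `expr`, and restores the previous RNG state so that
#' package functions are deterministic for a given `seed` without disturbing
#' the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# trapezoidal integral of y over t
trapz_int <- function(t, y) pracma::trapz(t, y)

# cumulative arc length of an n x 3 polyline (mm)
polyline_arclength <- function(points) {
  if (nrow(points) < 2) return(0)
  steps <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(steps))
}

# unit tangents of an n x 3 polyline by central differences
polyline_tangents <- function(points) {
  n <- nrow(points)
  d <- rbind(points[2, ] - points[1, ],
             points[seq(3, n), , drop = FALSE] -
               points[seq(1, n - 2), , drop = FALSE],
             points[n, ] - points[n - 1, ])
  d / pmax(sqrt(rowSums(d^2)), .Machine$double.eps)
}

# minimum distance from a single 3D point to a polyline (vertex-sampled)
point_polyline_distance <- function(p, points) {
  sqrt(min(rowSums(sweep(points, 2, p)^2)))
}

# linear interpolation of a profile (s -> value) at query arc lengths,
# constant extrapolation at the ends
profile_interp <- function(s, values, s_query) {
  approx(s, values, xout = s_query, rule = 2)$y
}

# smoothstep ramp: 0 at x <= 0, 1 at x >= 1, C1 in between
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# moving-average smoothing with edge shrinkage, window in samples (odd)
moving_average <- function(x, window) {
  if (window <= 1 || length(x) < 3) return(x)
  half <- floor(window / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# world coordinate of 0-based voxel indices (matrix n x 3)
voxel_to_world <- function(idx, spacing, origin) {
  sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)
}

# nearest voxel 0-based index of world points, clamped to the grid
world_to_voxel <- function(pts, spacing, origin, dims) {
  idx <- round(sweep(sweep(pts, 2, origin), 2, spacing, `/`))
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), dims[a] - 1)
  storage.mode(idx) <- "integer"
  idx
}

# linear (1-based) index from 0-based voxel triplets
voxel_linear_index <- function(idx, dims) {
  1L + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
}

# trilinear interpolation of a 3D array at world points (n x 3); points
# outside the grid take the value `outside`
trilinear_interp <- function(arr, spacing, origin, pts, outside = 0) {
  dims <- dim(arr)
  g <- sweep(sweep(pts, 2, origin), 2, spacing, `/`)  # 0-based fractional
  i0 <- floor(g)
  f <- g - i0
  out <- rep(outside, nrow(pts))
  ok <- g[, 1] >= 0 & g[, 1] <= dims[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= dims[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= dims[3] - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  i1 <- pmin(i0 + 1, matrix(rep(dims - 1, each = nrow(i0)), ncol = 3))
  val <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- if (cx == 0) i0[, 1] else i1[, 1]
    iy <- if (cy == 0) i0[, 2] else i1[, 2]
    iz <- if (cz == 0) i0[, 3] else i1[, 3]
    w <- (if (cx == 0) 1 - f[, 1] else f[, 1]) *
         (if (cy == 0) 1 - f[, 2] else f[, 2]) *
         (if (cz == 0) 1 - f[, 3] else f[, 3])
    val <- val + w * arr[1 + ix + dims[1] * (iy + dims[2] * iz)]
  }
  out[ok] <- val
  out
}

# bilinear interpolation of a 2D array at mm coordinates in the slice plane
bilinear_interp <- function(img, spacing, origin, pts, outside = 0) {
  dims <- dim(img)
  g <- sweep(sweep(pts, 2, origin[1:2]), 2, spacing[1:2], `/`)
  i0 <- floor(g)
  f <- g - i0
  out <- rep(outside, nrow(pts))
  ok <- g[, 1] >= 0 & g[, 1] <= dims[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= dims[2] - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  i1 <- cbind(pmin(i0[, 1] + 1, dims[1] - 1), pmin(i0[, 2] + 1, dims[2] - 1))
  v00 <- img[cbind(i0[, 1] + 1, i0[, 2] + 1)]
  v10 <- img[cbind(i1[, 1] + 1, i0[, 2] + 1)]
  v01 <- img[cbind(i0[, 1] + 1, i1[, 2] + 1)]
  v11 <- img[cbind(i1[, 1] + 1, i1[, 2] + 1)]
  out[ok] <- v00 * (1 - f[, 1]) * (1 - f[, 2]) + v10 * f[, 1] * (1 - f[, 2]) +
             v01 * (1 - f[, 1]) * f[, 2]       + v11 * f[, 1] * f[, 2]
  out
}

# resample a polyline at a fixed arc-length step (linear interpolation)
resample_polyline <- function(pts, step) {
  s <- polyline_arclength(pts)
  if (max(s) <= step) return(pts)
  sq <- seq(0, max(s), by = step)
  cbind(approx(s, pts[, 1], xout = sq)$y,
        approx(s, pts[, 2], xout = sq)$y,
        approx(s, pts[, 3], xout = sq)$y)
}

# separable 3D Gaussian blur (sigma in voxels, reflected edges)
gauss_blur3d <- function(arr, sigma = 1) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    reflect <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    out <- array(0, d)
    for (j in seq_along(k)) {
      sel <- reflect[seq_len(n) + j - 1]
      out <- out + k[j] * switch(ax,
        arr[sel, , , drop = FALSE],
        arr[, sel, , drop = FALSE],
        arr[, , sel, drop = FALSE])
    }
    arr <- out
  }
  arr
}

# deterministic hash of an R object via its deparsed source
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

# shoelace signed area of a closed 2D polygon (rows = vertices, not repeated)
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# polygon centroid (area-weighted)
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# TRUE where 2D points lie inside a closed polygon (even-odd rule)
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
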