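#' Sample luminal surface points from a phantom geometry
#'
#' Rings of points on the lumen surface along each branch, each carrying its
#' branch id and arc length from the bifurcation apex (CCA arc lengths run
#' proximally from the apex).
#'
#' @param geometry A `vessel_geometry`.
#' @param ds Axial sampling step (mm).
#' @param n_circ Points per ring.
#' @return Data frame `x`, `y`, `z` (mm), `branch`, `arclength_mm` (from
#'   the apex), `radius_mm`, and tangent components `tx`, `ty`, `tz`.
#' @export
sample_lumen_surface <- function(geometry, ds = 0.5, n_circ = 16) {
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[seq_len(n_circ)]
  rows <- list()
  for (bn in names(geometry$branches)) {
    b <- geometry$branches[[bn]]
    s_max <- max(b$arclength)
    s_q <- seq(0, s_max, by = ds)
    for (s in s_q) {
      i <- which.min(abs(b$arclength - s))
      t <- b$tangents[i, ]
      ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      e1 <- ref - sum(ref * t) * t
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(t[2] * e1[3] - t[3] * e1[2], t[3] * e1[1] - t[1] * e1[3],
              t[1] * e1[2] - t[2] * e1[1])
      r <- b$r_lumen[i]
      p <- b$centers[i, ]
      ring <- cbind(p[1] + r * (cos(th) * e1[1] + sin(th) * e2[1]),
                    p[2] + r * (cos(th) * e1[2] + sin(th) * e2[2]),
                    p[3] + r * (cos(th) * e1[3] + sin(th) * e2[3]))
      s_apex <- if (bn == "cca") s_max - s else s
      rows[[length(rows) + 1]] <- data.frame(
        x = ring[, 1], y = ring[, 2], z = ring[, 3], branch = bn,
        arclength_mm = s_apex, radius_mm = r,
        tx = t[1], ty = t[2], tz = t[3])
    }
  }
  do.call(rbind, rows)
}

# parallel-resistance flow split: proportional to the fourth power of the
# distal (reference) branch radius, as for uniform Poiseuille branches
branch_conductance <- function(branch) {
  branch$r_lumen[length(branch$r_lumen)]^4
}

#' Quasi-steady Poiseuille wall-shear-stress surrogate
#'
#' Stand-in for the CFD participant of an FSI simulation: at every time
#' point the wall shear stress magnitude on a surface point at arc length s
#' is `4 mu Q_branch(t) / (pi r(s)^3)` (Poiseuille), directed along the
#' local tangent. The inlet flow divides between ICA and ECA in proportion
#' to the fourth power of the distal branch radii (the parallel-resistance
#' rule for uniform Poiseuille branches). Outputs are flagged
#' `surrogate = TRUE`.
#'
#' @param geometry A `vessel_geometry`.
#' @param flow Inlet flow `waveform` (mL/s) over one cycle.
#' @param mu Blood dynamic viscosity (Pa s), default 0.00345.
#' @param ds,n_circ Surface sampling, see [sample_lumen_surface()].
#' @return A `wss_field`: `points` (surface table), `times` (s), `tau`
#'   (points x times x 3 array, Pa), `period`, `surrogate`.
#' @export
surrogate_wss_field <- function(geometry, flow, mu = blood_viscosity_pa_s,
                                ds = 0.5, n_circ = 16) {
  stopifnot(inherits(flow, "waveform"))
  surf <- sample_lumen_surface(geometry, ds, n_circ)
  if (any(surf$radius_mm <= 0)) stop("zero lumen radius: infinite WSS")
  g_ica <- branch_conductance(geometry$branches$ica)
  g_eca <- branch_conductance(geometry$branches$eca)
  split <- c(cca = 1, ica = g_ica / (g_ica + g_eca),
             eca = g_eca / (g_ica + g_eca))
  q_frac <- split[surf$branch]
  r_m <- surf$radius_mm * 1e-3
  tau_per_q <- 4 * mu / (pi * r_m^3) * 1e-6   # Pa per (mL/s)
  n_p <- nrow(surf)
  n_t <- length(flow$times)
  tau <- array(0, c(n_p, n_t, 3))
  tanv <- as.matrix(surf[, c("tx", "ty", "tz")])
  for (k in seq_len(n_t)) {
    mag <- tau_per_q * q_frac * flow$values[k]
    tau[, k, ] <- tanv * mag
  }
  structure(list(points = surf, times = flow$times, tau = tau,
                 period = flow$period, surrogate = TRUE),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("WSS field: %d surface points x %d time samples over T = %.3g s%s\n",
              nrow(x$points), length(x$times), x$period,
              if (isTRUE(x$surrogate)) " [surrogate]" else ""))
  invisible(x)
}

# tau component as an n_points x n_times matrix (dims kept for one point)
tau_component <- function(field, k) {
  matrix(field$tau[, , k], nrow = dim(field$tau)[1])
}

# per-point matrix of |tau| over time
tau_magnitude <- function(field) {
  sqrt(tau_component(field, 1)^2 + tau_component(field, 2)^2 +
       tau_component(field, 3)^2)
}

check_field_times <- function(field) {
  if (any(diff(field$times) <= 0)) stop("non-monotone field times")
  if (abs(field$times[1]) > 1e-9 ||
      field$times[length(field$times)] < field$period - 1e-9)
    stop("field must cover one full cycle [0, T]")
}

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) integral_0^T |tau_w| dt` per surface point, by trapezoidal
#' quadrature on the sample grid (the grid includes both cycle endpoints, so
#' the quadrature is consistent with the periodic definition).
#'
#' @param field A `wss_field`.
#' @return A `descriptor_map`: `points`, `values` (Pa), `name`.
#' @export
tawss <- function(field) {
  check_field_times(field)
  mag <- tau_magnitude(field)
  mag <- matrix(mag, nrow = dim(field$tau)[1])
  vals <- apply(mag, 1, function(y) trapz_int(field$times, y)) / field$period
  structure(list(points = field$points, values = vals, name = "TAWSS",
                 units = "Pa", surrogate = isTRUE(field$surrogate)),
            class = "descriptor_map")
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |integral tau dt| / integral |tau| dt)` per point, in
#' [0, 0.5]: 0 for unidirectional shear, 0.5 for purely oscillatory shear.
#' Points with zero total shear are returned as NA (masked), with a warning
#' when the whole field is zero.
#'
#' @param field A `wss_field`.
#' @param tol Relative tolerance below which total shear counts as zero.
#' @return A `descriptor_map` (dimensionless).
#' @export
osi <- function(field, tol = 1e-12) {
  check_field_times(field)
  t <- field$times
  ix <- apply(tau_component(field, 1), 1, function(y) trapz_int(t, y))
  iy <- apply(tau_component(field, 2), 1, function(y) trapz_int(t, y))
  iz <- apply(tau_component(field, 3), 1, function(y) trapz_int(t, y))
  imag <- apply(tau_magnitude(field), 1, function(y) trapz_int(t, y))
  vals <- rep(NA_real_, length(imag))
  ok <- imag > tol * max(imag, 1)
  vals[ok] <- 0.5 * (1 - sqrt(ix[ok]^2 + iy[ok]^2 + iz[ok]^2) / imag[ok])
  vals[ok] <- pmin(pmax(vals[ok], 0), 0.5)
  if (!any(ok)) warning("all-zero WSS field: OSI fully masked")
  structure(list(points = field$points, values = vals, name = "OSI",
                 units = "", surrogate = isTRUE(field$surrogate)),
            class = "descriptor_map")
}

#' Peak-systole WSS magnitude map
#'
#' `|tau_w|` at the time of maximum flow; on a tie the earliest time is
#' chosen.
#'
#' @param field A `wss_field`.
#' @param flow The inlet flow `waveform` defining peak systole.
#' @return A `descriptor_map` (Pa); attribute `t_peak` records the time.
#' @export
peak_systole_map <- function(field, flow) {
  t_star <- flow$times[which.max(flow$values)]  # earliest max by which.max
  k <- which.min(abs(field$times - t_star))
  mag <- tau_magnitude(field)
  out <- structure(list(points = field$points, values = mag[, k],
                        name = "peak-systole WSS", units = "Pa",
                        surrogate = isTRUE(field$surrogate)),
                   class = "descriptor_map")
  attr(out, "t_peak") <- field$times[k]
  out
}

#' @export
print.descriptor_map <- function(x, ...) {
  cat(sprintf("%s map: %d points, range [%.3g, %.3g] %s%s\n", x$name,
              length(x$values), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE), x$units,
              if (isTRUE(x$surrogate)) " [surrogate]" else ""))
  invisible(x)
}

#' Region-of-interest specification on the luminal surface
#'
#' @param branch Branch id (`"ica"`, `"eca"`, `"cca"`).
#' @param start Arc length (mm) from the bifurcation apex where the ROI
#'   starts.
#' @param length ROI length (mm), `> 0`. The default ROI is the
#'   apex-anchored 17 mm covering the stenotic ICA segment.
#' @return An `roi_spec`.
#' @export
roi_spec <- function(branch = "ica", start = 0, length = 17) {
  if (length <= 0) stop("ROI length must be positive")
  structure(list(branch = branch, start = start, length = length),
            class = "roi_spec")
}

#' ROI statistics of a descriptor map
#'
#' Unweighted mean and sample SD over surface points whose arc length from
#' the apex falls in `[start, start + length]` on the ROI branch; the raw
#' point values are returned for distribution (violin-style) plots.
#'
#' @param map A `descriptor_map`.
#' @param roi An [roi_spec()].
#' @return List `mean`, `sd`, `n`, `values`.
#' @export
roi_stats <- function(map, roi = roi_spec()) {
  sel <- map$points$branch == roi$branch &
    map$points$arclength_mm >= roi$start &
    map$points$arclength_mm <= roi$start + roi$length
  vals <- map$values[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("ROI contains no surface points")
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       n = length(vals), values = vals)
}

#' Export a WSS field as a long-format CSV
#'
#' Columns `point_id, x, y, z, branch, arclength_mm, t_s, taux, tauy, tauz`.
#'
#' @param field A `wss_field`.
#' @param path Output file.
#' @export
write_wss_field <- function(field, path) {
  n_p <- nrow(field$points)
  n_t <- length(field$times)
  df <- data.frame(
    point_id = rep(seq_len(n_p), times = n_t),
    x = rep(field$points$x, n_t), y = rep(field$points$y, n_t),
    z = rep(field$points$z, n_t),
    branch = rep(field$points$branch, n_t),
    arclength_mm = rep(field$points$arclength_mm, n_t),
    t_s = rep(field$times, each = n_p),
    taux = as.vector(field$tau[, , 1]),
    tauy = as.vector(field$tau[, , 2]),
    tauz = as.vector(field$tau[, , 3]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a WSS field from the long-format CSV
#'
#' Accepts externally computed WSS time series in the same layout, so all
#' descriptor operations can run on non-surrogate fields unchanged.
#'
#' @param path CSV file written by [write_wss_field()] or an external solver.
#' @param period Cycle period (s); defaults to the last time sample.
#' @return A `wss_field` with `surrogate = FALSE`.
#' @export
read_wss_field <- function(path, period = NULL) {
  df <- read.csv(path)
  times <- sort(unique(df$t_s))
  ids <- sort(unique(df$point_id))
  n_p <- length(ids); n_t <- length(times)
  first <- df[df$t_s == times[1], ]
  first <- first[order(first$point_id), ]
  tau <- array(0, c(n_p, n_t, 3))
  for (k in seq_len(n_t)) {
    blk <- df[df$t_s == times[k], ]
    blk <- blk[order(blk$point_id), ]
    tau[, k, 1] <- blk$taux; tau[, k, 2] <- blk$tauy; tau[, k, 3] <- blk$tauz
  }
  structure(list(points = first[, c("x", "y", "z", "branch",
                                    "arclength_mm")],
                 times = times, tau = tau,
                 period = period %||% times[n_t], surrogate = FALSE),
            class = "wss_field")
}
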