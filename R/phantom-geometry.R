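#' Default phantom configuration
#'
#' Parameters of the synthetic carotid-bifurcation phantom: a common carotid
#' artery (CCA) running along +z, branching at the apex into an internal
#' carotid artery (ICA) with an optional smooth cosine-tapered stenosis and
#' an external carotid artery (ECA). Radii follow typical adult carotid
#' calibres (CCA 3.1 mm, distal ICA 2.5 mm, ECA 2.0 mm lumen radius) and the
#' wall is 1 mm thick; in the stenotic segment the outer wall keeps the
#' healthy calibre so that the band between lumen and outer wall thickens
#' into a plaque-bearing region.
#'
#' @param ... Named overrides of any default parameter.
#' @return Named list of phantom parameters.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    cca_length = 20,          # mm, inlet to apex
    ica_length = 25,          # mm, apex to outlet
    eca_length = 20,          # mm
    r_cca = 3.1,              # mm lumen radius
    r_ica = 2.5,              # mm distal ICA lumen radius
    r_eca = 2.0,              # mm
    wall_thickness = 1.0,     # mm
    ica_angle = 22,           # degrees from CCA direction, bend in x-z plane
    eca_angle = -28,          # degrees
    turn_length = 0.3,        # mm over which a branch bends to its angle
                              # (short: branches leave the apex at a clear
                              # wedge angle, as real bifurcations do)
    blend_length = 4,         # mm over which branch radius blends from CCA
    stenosis_fraction = 0.81, # of distal ICA radius, in [0, 1)
    stenosis_center = 8,      # mm from apex along the ICA
    stenosis_halfwidth = 5,   # mm half-width of the cosine taper
    stenosis_eccentricity = 0,# 0 = concentric lumen narrowing
    outer_bulge = 1.5,        # mm outward (expansive) remodelling of the
                              # outer wall over the stenosis taper
    bulb_amp = 0.6,           # mm carotid-sinus (bulb) widening at the ICA
    bulb_center = 1.5,        # mm past the apex
    bulb_width = 2.0,         # mm Gaussian width of the bulb
    axis_step = 0.15          # mm axis sampling step
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown phantom parameter(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Build a synthetic carotid bifurcation geometry
#'
#' Sweeps circular cross-sections along straight-plus-arc branch axes. The
#' ICA lumen radius profile is `base(s) * (1 - f * taper(s))` where `taper`
#' is a cosine bump centred at `stenosis_center` so that the minimum lumen
#' radius equals the distal ICA radius times `1 - stenosis_fraction`. The
#' outer wall follows the unstenosed profile plus `wall_thickness`, so the
#' wall band thickens across the stenosis.
#'
#' @param config List from [phantom_config()].
#' @return A `vessel_geometry`: per-branch axis polylines (mm), arc lengths,
#'   lumen/outer radius profiles, lumen centre polylines (equal to the axis
#'   unless the stenosis is eccentric), and the apex point.
#' @export
make_bifurcation_geometry <- function(config = phantom_config()) {
  cfg <- config
  if (cfg$r_cca <= 0 || cfg$r_ica <= 0 || cfg$r_eca <= 0)
    stop("lumen radii must be positive")
  if (cfg$wall_thickness <= 0) stop("wall thickness must be positive")
  if (cfg$stenosis_fraction < 0 || cfg$stenosis_fraction >= 1)
    stop("stenosis_fraction must lie in [0, 1)")
  if (abs(cfg$ica_angle) <= 0 || abs(cfg$eca_angle) <= 0)
    stop("branch angles must be non-zero")

  apex <- c(0, 0, cfg$cca_length)
  ds <- cfg$axis_step

  bent_axis <- function(angle_deg, length) {
    # arc from vertical to angle_deg over turn_length, then straight
    n <- max(ceiling(length / ds), 2)
    s <- seq(0, length, length.out = n + 1)
    step <- length / n
    phi <- (angle_deg * pi / 180) * smoothstep(s / cfg$turn_length)
    dirs <- cbind(sin(phi), 0, cos(phi))
    pts <- apply(dirs * step, 2, cumsum)
    pts <- rbind(c(0, 0, 0), pts[-nrow(pts), , drop = FALSE])
    sweep(pts, 2, apex, `+`)
  }

  n_cca <- max(ceiling(cfg$cca_length / ds), 2)
  cca_pts <- cbind(0, 0, seq(0, cfg$cca_length, length.out = n_cca + 1))
  ica_pts <- bent_axis(cfg$ica_angle, cfg$ica_length)
  eca_pts <- bent_axis(cfg$eca_angle, cfg$eca_length)

  branch <- function(points, r_distal, stenosed) {
    s <- polyline_arclength(points)
    base <- r_distal + (cfg$r_cca - r_distal) *
      (1 - smoothstep(s / cfg$blend_length))
    if (stenosed && cfg$bulb_amp > 0) {
      # carotid sinus at the ICA origin: compactly supported cosine bump so
      # the bulb cannot perturb the stenosis throat radius
      u <- (s - cfg$bulb_center) / (2 * cfg$bulb_width)
      inb <- abs(u) <= 1
      base[inb] <- base[inb] + cfg$bulb_amp * 0.5 * (1 + cos(pi * u[inb]))
    }
    taper <- rep(0, length(s))
    if (stenosed && cfg$stenosis_fraction > 0) {
      u <- (s - cfg$stenosis_center) / cfg$stenosis_halfwidth
      inb <- abs(u) <= 1
      taper[inb] <- 0.5 * (1 + cos(pi * u[inb]))
      # the throat may fall between axis samples: snap the nearest sample to
      # the exact minimum so the configured minimum radius is realized
      if (any(inb)) taper[which.min(abs(u))] <- 1
    }
    r_lumen <- base * (1 - cfg$stenosis_fraction * taper)
    r_outer <- base + cfg$wall_thickness + cfg$outer_bulge * taper
    centers <- points
    if (stenosed && cfg$stenosis_eccentricity > 0) {
      offset <- cfg$stenosis_eccentricity * (base - r_lumen)
      centers[, 2] <- centers[, 2] + offset
    }
    list(points = points, centers = centers, arclength = s,
         r_lumen = r_lumen, r_outer = r_outer,
         tangents = polyline_tangents(points))
  }

  br <- list(
    cca = branch(cca_pts, cfg$r_cca, stenosed = FALSE),
    ica = branch(ica_pts, cfg$r_ica, stenosed = TRUE),
    eca = branch(eca_pts, cfg$r_eca, stenosed = FALSE)
  )
  structure(list(branches = br, apex_point = apex, config = cfg),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cfg <- x$config
  cat("Carotid bifurcation geometry\n")
  cat(sprintf("  CCA %.0f mm (r %.2f), ICA %.0f mm (r %.2f), ECA %.0f mm (r %.2f)\n",
              cfg$cca_length, cfg$r_cca, cfg$ica_length, cfg$r_ica,
              cfg$eca_length, cfg$r_eca))
  cat(sprintf("  ICA stenosis %.0f%% at %.1f mm past the apex\n",
              100 * cfg$stenosis_fraction, cfg$stenosis_center))
  invisible(x)
}

# local orthonormal frame at arc length s on a branch: list(point, tangent,
# e1 (approximately +y), e2)
branch_frame <- function(geometry, branch, s) {
  b <- geometry$branches[[branch]]
  i <- which.min(abs(b$arclength - s))
  t <- b$tangents[i, ]
  ref <- c(0, 1, 0)
  e1 <- ref - sum(ref * t) * t
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t[2] * e1[3] - t[3] * e1[2],
          t[3] * e1[1] - t[1] * e1[3],
          t[1] * e1[2] - t[2] * e1[1])
  list(point = b$points[i, ], tangent = t, e1 = e1, e2 = e2,
       r_lumen = b$r_lumen[i], r_outer = b$r_outer[i])
}

#' Place an ellipsoidal inclusion inside the wall band
#'
#' Positions an ellipsoid in the thickened wall at arc length `s` along a
#' branch, oriented with its third semi-axis along the local vessel tangent
#' so that elongated inclusions follow the vessel. `depth` is the radial
#' distance of the centre from the lumen axis (defaults to mid-band).
#'
#' @param geometry A `vessel_geometry`.
#' @param branch `"cca"`, `"ica"` or `"eca"`.
#' @param s Arc length (mm) along the branch.
#' @param angle_deg Circumferential position (degrees; 0 = +y direction).
#' @param semi_axes Length-3 semi-axes (mm): two cross-vessel, one along it.
#' @param depth Radial centre distance (mm) from the axis, or `NULL`.
#' @param name Region name used in error messages.
#' @return An ellipsoid spec: `center`, `semi_axes`, `axes` (3x3 rotation,
#'   columns = local axes), `name`.
#' @export
place_wall_inclusion <- function(geometry, branch, s, angle_deg, semi_axes,
                                 depth = NULL, name = "inclusion") {
  fr <- branch_frame(geometry, branch, s)
  if (is.null(depth)) depth <- (fr$r_lumen + fr$r_outer) / 2
  a <- angle_deg * pi / 180
  dir <- cos(a) * fr$e1 + sin(a) * fr$e2
  center <- fr$point + depth * dir
  u <- dir
  w <- fr$tangent
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(center = center, semi_axes = semi_axes,
       axes = cbind(u, v, w), name = name)
}

#' Plaque component specification
#'
#' @param lipid,calcification Lists of ellipsoid specs (see
#'   [place_wall_inclusion()]); ellipsoids may also be given directly as
#'   `list(center=, semi_axes=, axes=NULL, name=)` in world coordinates.
#' @param fibrous_cap_min_target Design minimum cap thickness (mm), recorded
#'   for provenance only.
#' @return A `plaque_spec` list.
#' @export
plaque_spec <- function(lipid = list(), calcification = list(),
                        fibrous_cap_min_target = NA_real_) {
  structure(list(lipid = lipid, calcification = calcification,
                 fibrous_cap_min_target = fibrous_cap_min_target),
            class = "plaque_spec")
}

#' Default plaque layouts emulating three stenosis cases
#'
#' Three phantom cases with similar stenosis degrees (81, 83 and 82 percent)
#' but deliberately different plaque composition: case 1 a moderate lipid
#' pool with a small calcification, case 2 calcification-dominant, case 3
#' lipid-dominant. Inclusions are placed inside the thickened stenotic wall
#' band of the ICA.
#'
#' @param case Integer 1, 2 or 3.
#' @return List with `config` (phantom parameters) and a function
#'   `plaque(geometry)` returning the [plaque_spec()] for that geometry.
#' @export
phantom_case <- function(case) {
  stopifnot(case %in% 1:3)
  f <- c(0.81, 0.83, 0.82)[case]
  cfg <- phantom_config(stenosis_fraction = f)
  inc <- function(g, s, a, semi, d, nm)
    place_wall_inclusion(g, "ica", s, a, semi, depth = d, name = nm)
  plaque_fun <- switch(case,
    function(g) plaque_spec(
      lipid = list(
        inc(g, 8.0,   0, c(1.35, 1.15, 3.2), 3.15, "lipid-1"),
        inc(g, 7.6,  55, c(0.95, 0.85, 2.0), 3.35, "lipid-2")),
      calcification = list(
        inc(g, 5.5, 180, c(0.80, 0.70, 1.2), 3.30, "calc-1")),
      fibrous_cap_min_target = 0.75),
    function(g) plaque_spec(
      lipid = list(
        inc(g, 8.0,  15, c(1.25, 1.00, 3.0), 3.40, "lipid-1"),
        inc(g, 7.6, 325, c(1.00, 0.85, 2.0), 3.40, "lipid-2")),
      calcification = list(
        inc(g, 8.0, 180, c(1.45, 1.15, 3.4), 3.15, "calc-1"),
        inc(g, 7.8, 230, c(1.25, 1.05, 2.7), 3.20, "calc-2"),
        inc(g, 8.4, 135, c(1.10, 0.95, 2.3), 3.30, "calc-3")),
      fibrous_cap_min_target = 1.16),
    function(g) plaque_spec(
      lipid = list(
        inc(g, 8.0,   0, c(1.35, 1.20, 3.4), 3.15, "lipid-1"),
        inc(g, 7.8,  45, c(1.25, 1.10, 2.7), 3.30, "lipid-2"),
        inc(g, 8.3, 300, c(1.25, 1.10, 2.8), 3.15, "lipid-3"),
        inc(g, 7.6, 120, c(1.00, 0.85, 2.0), 3.35, "lipid-4")),
      calcification = list(
        inc(g, 5.5, 195, c(0.85, 0.75, 1.4), 3.35, "calc-1")),
      fibrous_cap_min_target = 0.65)
  )
  list(config = cfg, plaque = plaque_fun)
}
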