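#' Elastic material table for plaque tissues
#'
#' Linear-elastic constants per tissue: arterial (fibrous) wall 0.6 MPa,
#' calcification 10 MPa, lipid 0.02 MPa, Poisson ratio 0.48 throughout.
#'
#' @return Data frame `class`, `E_MPa`, `nu`.
#' @export
material_table <- function() {
  data.frame(class = c("wall", "lipid", "calcification"),
             E_MPa = c(0.6, 0.02, 10),
             nu = c(0.48, 0.48, 0.48),
             stringsAsFactors = FALSE)
}

# signed volumes (mm^3) of tets given nodes (n x 3) and tets (m x 4)
tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
   nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

#' Tetrahedralize the phantom wall band
#'
#' Structured tetrahedralization: the wall band (between lumen and outer
#' surfaces) is voxelized at a pitch derived from `target_edge` and every
#' occupied cell is split into six positively oriented tetrahedra sharing
#' the cell's main diagonal (Kuhn subdivision). Cell edges, face diagonals
#' and body diagonals give edge lengths of 1, sqrt(2) and sqrt(3) times the
#' pitch, so the median edge tracks the requested element size; each cell is
#' filled exactly, making the total mesh volume equal the voxelized band
#' volume.
#'
#' @param geometry A `vessel_geometry`.
#' @param target_edge Target element edge length (mm), default 0.3.
#' @return List `nodes` (n x 3 mm), `tets` (m x 4, 1-based, positive
#'   orientation), `pitch`.
#' @export
mesh_phantom_wall <- function(geometry, target_edge = 0.3) {
  if (target_edge <= 0) stop("target_edge must be positive")
  if (geometry$config$wall_thickness <= 0)
    stop("degenerate zero-thickness wall")
  pitch <- target_edge / 1.2
  grid <- default_grid(geometry, spacing = pitch, margin = 0.5)
  lumen <- array(FALSE, grid$dims)
  outer_m <- array(FALSE, grid$dims)
  for (b in geometry$branches) {
    lumen <- sweep_tube_mask(lumen, b$centers, b$r_lumen, grid$spacing,
                             grid$origin)
    outer_m <- sweep_tube_mask(outer_m, b$points, b$r_outer, grid$spacing,
                               grid$origin)
  }
  wall <- outer_m & !lumen
  if (!any(wall)) stop("degenerate wall band: no voxels")
  occ <- which(wall, arr.ind = TRUE) - 1L  # 0-based cell indices

  # node grid: cell (i,j,k) owns corners (i..i+1, j..j+1, k..k+1)
  nd <- grid$dims + 1L
  node_id <- function(i, j, k) 1L + i + nd[1] * (j + nd[2] * k)
  corner <- function(di, dj, dk) node_id(occ[, 1] + di, occ[, 2] + dj,
                                         occ[, 3] + dk)
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  # six tets around the main diagonal c000-c111 (all positively oriented)
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c110, c010, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c011, c001, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c101, c100, c111)
  )
  used <- sort(unique(as.vector(tets)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  u0 <- used - 1L
  nodes <- cbind(u0 %% nd[1], (u0 %/% nd[1]) %% nd[2], u0 %/% (nd[1] * nd[2]))
  # cell corners sit at voxel-centre - pitch/2 offsets
  nodes <- sweep(nodes * pitch, 2, grid$origin - pitch / 2, `+`)
  vol <- tet_signed_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, ] <- tets[neg, c(1, 3, 2, 4)]
  list(nodes = nodes, tets = tets, pitch = pitch)
}

#' Map voxel tissue labels to mesh material properties
#'
#' Per-element tissue class is the label at the voxel containing the
#' element centroid; Young's modulus and Poisson ratio come from the
#' material table. Elements whose centroid falls in lumen or background are
#' assigned arterial wall properties (their count is reported via a
#' message). The lookup is idempotent: re-mapping a mapped mesh with the
#' same labels changes nothing.
#'
#' @param mesh List `nodes`, `tets` (see [mesh_phantom_wall()]).
#' @param labels A `label_volume`.
#' @param table Material table (see [material_table()]).
#' @return A `material_mesh`: `nodes`, `tets`, `E_MPa`, `nu`, `tissue`
#'   per element.
#' @export
map_materials_to_mesh <- function(mesh, labels, table = material_table()) {
  cent <- tet_centroids(mesh$nodes, mesh$tets)
  dims <- dim(labels$labels)
  idx <- round(sweep(sweep(cent, 2, labels$origin), 2, labels$spacing, `/`))
  out_of_grid <- idx[, 1] < 0 | idx[, 1] > dims[1] - 1 |
                 idx[, 2] < 0 | idx[, 2] > dims[2] - 1 |
                 idx[, 3] < 0 | idx[, 3] > dims[3] - 1
  if (any(out_of_grid))
    stop("mesh extends outside the label grid; offending elements: ",
         paste(head(which(out_of_grid), 10), collapse = ", "),
         if (sum(out_of_grid) > 10) " ..." else "")
  storage.mode(idx) <- "integer"
  lab <- labels$labels[voxel_linear_index(idx, dims)]
  cls <- names(tissue_codes)[match(lab, tissue_codes)]
  fallback <- !cls %in% table$class
  if (any(fallback))
    message(sum(fallback),
            " element centroid(s) in lumen/background assigned wall tissue")
  cls[fallback] <- "wall"
  row <- match(cls, table$class)
  structure(list(nodes = mesh$nodes, tets = mesh$tets,
                 E_MPa = table$E_MPa[row], nu = table$nu[row],
                 tissue = cls),
            class = "material_mesh")
}

#' @export
print.material_mesh <- function(x, ...) {
  cat(sprintf("Material mesh: %d nodes, %d tets\n",
              nrow(x$nodes), nrow(x$tets)))
  print(table(x$tissue))
  invisible(x)
}

#' Smooth material transitions between components
#'
#' Replaces each element's Young's modulus by the inverse-distance-weighted
#' average of neighbouring elements' moduli within `radius` of its centroid,
#' computed in log-modulus space so the 500-fold stiffness contrast between
#' calcification and lipid does not dominate; Poisson ratios are unchanged.
#' `radius = 0` is the identity.
#'
#' @param mm A `material_mesh`.
#' @param radius Neighbourhood radius (mm), default 0.6.
#' @return A `material_mesh` with smoothed `E_MPa`.
#' @export
smooth_transition <- function(mm, radius = 0.6) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(mm)
  cent <- tet_centroids(mm$nodes, mm$tets)
  n <- nrow(cent)
  logE <- log(mm$E_MPa)
  # bucket centroids on a grid of cell size = radius
  cell <- floor(sweep(cent, 2, apply(cent, 2, min)) / radius)
  key <- cell[, 1] + 1e4 * cell[, 2] + 1e8 * cell[, 3]
  buckets <- split(seq_len(n), key)
  key_of <- function(cl) cl[1] + 1e4 * cl[2] + 1e8 * cl[3]
  newE <- numeric(n)
  for (b in buckets) {
    cl <- cell[b[1], ]
    cand <- integer(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      kk <- as.character(key_of(cl + c(dx, dy, dz)))
      if (!is.null(buckets[[kk]])) cand <- c(cand, buckets[[kk]])
    }
    pc <- cent[cand, , drop = FALSE]
    for (i in b) {
      d2 <- (pc[, 1] - cent[i, 1])^2 + (pc[, 2] - cent[i, 2])^2 +
            (pc[, 3] - cent[i, 3])^2
      keep <- d2 <= radius^2
      w <- 1 / pmax(sqrt(d2[keep]), 1e-6)
      newE[i] <- exp(sum(w * logE[cand[keep]]) / sum(w))
    }
  }
  mm$E_MPa <- newE
  mm
}

#' Write a material mesh in legacy VTK ASCII format
#'
#' Unstructured grid with per-cell scalar fields `E_MPa`, `nu` and
#' `tissue_id`, loadable by standard mesh viewers.
#'
#' @param mm A `material_mesh`.
#' @param path Output `.vtk` file.
#' @export
write_material_mesh_vtk <- function(mm, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("# vtk DataFile Version 3.0",
               "plaquescan material mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mm$nodes))), con)
  write.table(format(mm$nodes, trim = TRUE), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  m <- nrow(mm$tets)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  write.table(cbind(4L, mm$tets - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS E_MPa float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mm$E_MPa, trim = TRUE), con)
  writeLines(c("SCALARS nu float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mm$nu, trim = TRUE), con)
  writeLines(c("SCALARS tissue_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(tissue_codes[mm$tissue]), con)
  invisible(path)
}
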