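small_mesh_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    geom <- straight_tube_geometry(r = 2, h = 1.5, len = 8)
    mesh <- mesh_phantom_wall(geom, target_edge = 0.6)
    cache <<- list(geom = geom, mesh = mesh)
    cache
  }
})

test_that("wall mesh meets the element-size and orientation contracts", {
  fx <- small_mesh_fixture()
  mesh <- fx$mesh
  # positive orientation throughout
  vol <- plaquescan:::tet_signed_volumes(mesh$nodes, mesh$tets)
  expect_true(all(vol > 0))
  # median edge length within 25% of the target
  e <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)],
             mesh$tets[, c(1, 4)], mesh$tets[, c(2, 3)],
             mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  e <- unique(t(apply(e, 1, sort)))
  len <- sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2))
  expect_gt(median(len), 0.75 * 0.6)
  expect_lt(median(len), 1.25 * 0.6)
  # total tet volume matches the voxelized band volume within 10%
  lab <- rasterize_labels(fx$geom, grid = mesh$pitch)
  v_band <- component_volume(lab, "wall")
  expect_lt(abs(sum(vol) - v_band) / v_band, 0.10)
  expect_error(mesh_phantom_wall(fx$geom, target_edge = 0), "positive")
})

test_that("default element-size convention (0.3 mm) is met on a small wall", {
  geom <- straight_tube_geometry(r = 1.2, h = 0.8, len = 3)
  mesh <- mesh_phantom_wall(geom, target_edge = 0.3)
  e <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)],
             mesh$tets[, c(1, 4)], mesh$tets[, c(2, 3)],
             mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  e <- unique(t(apply(e, 1, sort)))
  len <- sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2))
  expect_gt(median(len), 0.225)
  expect_lt(median(len), 0.375)
})

test_that("material lookup assigns table moduli by centroid tissue", {
  geom <- straight_tube_geometry(r = 2, h = 3, len = 10)
  lipid <- list(center = c(0, 3.5, 5), semi_axes = c(0.6, 0.6, 1.2),
                axes = NULL, name = "lipid")
  calc <- list(center = c(0, -3.5, 5), semi_axes = c(0.6, 0.6, 1.2),
               axes = NULL, name = "calc")
  lab <- rasterize_labels(geom, plaque_spec(lipid = list(lipid),
                                            calcification = list(calc)),
                          grid = 0.3)
  mesh <- mesh_phantom_wall(geom, target_edge = 0.6)
  mm <- map_materials_to_mesh(mesh, lab)
  expect_true(all(mm$nu == 0.48))
  expect_setequal(unique(mm$E_MPa), c(0.6, 0.02, 10))
  expect_equal(unname(sort(unique(mm$E_MPa[mm$tissue == "lipid"]))), 0.02)
  expect_equal(unname(sort(unique(mm$E_MPa[mm$tissue == "calcification"]))),
               10)
  # idempotence: re-mapping a mapped mesh changes nothing
  mm2 <- map_materials_to_mesh(mm, lab)
  expect_identical(mm2$E_MPa, mm$E_MPa)
  expect_identical(mm2$tissue, mm$tissue)
  # class-wise element volume fractions track label volume fractions
  vol <- plaquescan:::tet_signed_volumes(mm$nodes, mm$tets)
  for (cls in c("lipid", "calcification")) {
    f_mesh <- sum(vol[mm$tissue == cls]) / sum(vol)
    f_lab <- component_volume(lab, cls) /
      sum(vapply(c("wall", "lipid", "calcification"),
                 function(cl) component_volume(lab, cl), 0))
    expect_lt(abs(f_mesh - f_lab) / f_lab, 0.10)
  }
})

test_that("all-wall phantom maps every element to 0.6 MPa", {
  fx <- small_mesh_fixture()
  lab <- rasterize_labels(fx$geom, grid = 0.3)
  mm <- map_materials_to_mesh(fx$mesh, lab)
  expect_true(all(mm$E_MPa == 0.6))
  expect_true(all(mm$tissue == "wall"))
})

test_that("a mesh outside the label grid is rejected with element ids", {
  fx <- small_mesh_fixture()
  lab <- rasterize_labels(fx$geom, grid = 0.3)
  mesh_far <- fx$mesh
  mesh_far$nodes <- mesh_far$nodes + 100
  expect_error(map_materials_to_mesh(mesh_far, lab), "outside")
})

test_that("transition smoothing is a bounded monotone log-space average", {
  # two-material half-space on a regular slab mesh
  nodes <- as.matrix(expand.grid(x = 0:6, y = 0:2, z = 0:2)) * 0.5
  cells <- as.matrix(expand.grid(x = 0:5, y = 0:1, z = 0:1))
  nd <- c(7, 3, 3)
  nid <- function(i, j, k) 1 + i + nd[1] * (j + nd[2] * k)
  tets <- NULL
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]; k <- cells[r, 3]
    c0 <- nid(i, j, k); c1 <- nid(i + 1, j, k); c2 <- nid(i + 1, j + 1, k)
    c3 <- nid(i, j + 1, k); c4 <- nid(i, j, k + 1); c5 <- nid(i + 1, j, k + 1)
    c6 <- nid(i + 1, j + 1, k + 1); c7 <- nid(i, j + 1, k + 1)
    tets <- rbind(tets,
                  c(c0, c1, c2, c6), c(c0, c2, c3, c6), c(c0, c3, c7, c6),
                  c(c0, c7, c4, c6), c(c0, c4, c5, c6), c(c0, c5, c1, c6))
  }
  cent <- plaquescan:::tet_centroids(nodes, tets)
  E <- ifelse(cent[, 1] < 1.5, 0.02, 0.6)
  mm <- structure(list(nodes = nodes, tets = tets, E_MPa = E,
                       nu = rep(0.48, nrow(tets)),
                       tissue = ifelse(E == 0.02, "lipid", "wall")),
                  class = "material_mesh")
  # radius 0 is the identity
  expect_identical(smooth_transition(mm, 0)$E_MPa, mm$E_MPa)
  # homogeneous input is unchanged under any radius
  hom <- mm; hom$E_MPa <- rep(0.6, nrow(tets))
  expect_equal(smooth_transition(hom, 1)$E_MPa, hom$E_MPa,
               tolerance = 1e-12)
  sm <- smooth_transition(mm, 0.8)
  # bounded by the input range (geometric-mean bound)
  expect_true(all(sm$E_MPa >= 0.02 - 1e-12 & sm$E_MPa <= 0.6 + 1e-12))
  # monotone across the interface along x
  ord <- order(cent[, 1])
  prof <- tapply(sm$E_MPa, round(cent[, 1], 6), mean)
  expect_true(all(diff(prof[order(as.numeric(names(prof)))]) > -1e-9))
  # nu untouched
  expect_identical(sm$nu, mm$nu)
  expect_error(smooth_transition(mm, -1), "radius")
})

test_that("VTK export writes a parseable unstructured grid", {
  fx <- small_mesh_fixture()
  lab <- rasterize_labels(fx$geom, grid = 0.3)
  mm <- map_materials_to_mesh(fx$mesh, lab)
  f <- tempfile(fileext = ".vtk")
  write_material_mesh_vtk(mm, f)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  np <- as.integer(strsplit(lines[5], " ")[[1]][2])
  expect_equal(np, nrow(mm$nodes))
  expect_true(any(grepl("^SCALARS E_MPa", lines)))
})
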