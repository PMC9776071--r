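test_that("cost volume follows the inverse-intensity formula", {
  n <- 6
  ch <- array(0.5, c(n, n, n))
  ch[1, 1, 1] <- 0; ch[n, n, n] <- 1  # pin the normalization range
  st <- contrast_stack(list(TOF = ch), spacing = c(1, 1, 1))
  cv <- build_cost_volume(st)
  expect_equal(cv$costs[2, 2, 2], 1 / 0.55, tolerance = 1e-12)
  expect_true(all(cv$costs <= 1 / 0.05 + 1e-9))
  flat <- contrast_stack(list(TOF = array(1, c(4, 4, 4))), c(1, 1, 1))
  expect_error(build_cost_volume(flat), "constant")
  expect_error(build_cost_volume(st, "T1W"), "channel")
})

test_that("a bright tube is cheaper inside than outside", {
  fx <- phantom_fixture(1, spacing = 0.4, noise_sd = 0)
  cv <- build_cost_volume(fx$stack)
  lum <- fx$labels$labels == tissue_codes[["lumen"]]
  expect_lt(max(cv$costs[lum]), min(cv$costs[!lum]))
})

test_that("least-cost path is straight on uniform cost and symmetric", {
  ch <- array(0, c(9, 5, 5))
  ch[1, 1, 1] <- 1  # normalization range; cost becomes uniform 1/.05 vs 1/1.05
  ch[, 3, 3] <- 1   # bright straight corridor on the x axis
  st <- contrast_stack(list(TOF = ch), spacing = c(1, 1, 1))
  cv <- build_cost_volume(st)
  p <- least_cost_path(cv, c(0, 2, 2), c(8, 2, 2))
  expect_equal(nrow(p$points), 9)
  expect_true(all(p$points[, 2] == 2 & p$points[, 3] == 2))
  expect_equal(p$total_cost, 8 * (1 / 1.05), tolerance = 1e-9)
  # seed swap: reversed path, equal cost
  pr <- least_cost_path(cv, c(8, 2, 2), c(0, 2, 2))
  expect_equal(pr$points[rev(seq_len(nrow(pr$points))), ], p$points,
               ignore_attr = TRUE)
  expect_equal(pr$total_cost, p$total_cost)
})

test_that("path follows a cheap L-shaped corridor (exhaustive check)", {
  img <- matrix(0.05, 5, 5)
  img[, 1] <- 0.95; img[5, ] <- 0.95  # L corridor
  ch <- array(img, c(5, 5, 1))
  st <- contrast_stack(list(TOF = ch), spacing = c(1, 1, 1))
  cv <- build_cost_volume(st)
  p <- least_cost_path(cv, c(0, 0, 0), c(4, 4, 0))
  corridor <- img >= 0.9
  on_corr <- corridor[cbind(p$points[, 1] + 1, p$points[, 2] + 1)]
  expect_true(all(on_corr))
  # independent oracle: Bellman-Ford relaxation on the same grid graph
  d_bf <- bellman_ford_grid(cv$costs, cv$spacing, c(0, 0, 0), c(4, 4, 0))
  expect_equal(p$total_cost, d_bf, tolerance = 1e-9)
})

test_that("Dijkstra equals Bellman-Ford on random grids up to 6x6x3", {
  set.seed(42)
  for (rep in 1:6) {
    dims <- c(sample(2:6, 1), sample(2:6, 1), sample(1:3, 1))
    costs <- array(runif(prod(dims), 0.1, 2), dims)
    cv <- structure(list(costs = costs, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)), class = "cost_volume")
    src <- c(0, 0, 0)
    dst <- dims - 1
    p <- least_cost_path(cv, src, dst)
    d_bf <- bellman_ford_grid(costs, c(1, 1, 1), src, dst)
    expect_equal(p$total_cost, d_bf, tolerance = 1e-9)
  }
})

test_that("path cost is monotone under uniform cost inflation", {
  set.seed(3)
  costs <- array(runif(60, 0.2, 1), c(5, 4, 3))
  cv1 <- structure(list(costs = costs, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)), class = "cost_volume")
  cv2 <- structure(list(costs = 2.5 * costs, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)), class = "cost_volume")
  p1 <- least_cost_path(cv1, c(0, 0, 0), c(4, 3, 2))
  p2 <- least_cost_path(cv2, c(0, 0, 0), c(4, 3, 2))
  expect_equal(p2$total_cost, 2.5 * p1$total_cost, tolerance = 1e-9)
})

test_that("bifurcation extraction recovers both paths and the apex", {
  fx <- phantom_fixture(1, spacing = 0.5, noise_sd = 0.05)
  cv <- build_cost_volume(fx$stack, medialness = TRUE, sigma = 1)
  g <- fx$geom
  ends <- rbind(g$branches$cca$points[1, ],
                g$branches$ica$points[nrow(g$branches$ica$points), ],
                g$branches$eca$points[nrow(g$branches$eca$points), ])
  vox <- plaquescan:::world_to_voxel(ends, fx$labels$spacing,
                                     fx$labels$origin, dim(fx$labels$labels))
  cl <- extract_bifurcation_centerlines(cv, vox[1, ], vox[2, ], vox[3, ])
  # both paths start at the CCA seed coordinate
  expect_equal(cl$ica$points[1, ], cl$eca$points[1, ], ignore_attr = TRUE)
  seed_world <- plaquescan:::voxel_to_world(matrix(vox[1, ], 1),
                                            fx$labels$spacing,
                                            fx$labels$origin)
  expect_equal(cl$ica$points[1, ], as.vector(seed_world),
               ignore_attr = TRUE)
  # apex within 2 voxels of ground truth
  expect_lt(sqrt(sum((cl$apex - g$apex_point)^2)), 2 * 0.5)
  # on this noise level the path stays within a voxel diagonal of the axis
  axis <- rbind(g$branches$cca$points, g$branches$ica$points)
  dmax <- max(apply(cl$ica$points, 1, function(p)
    plaquescan:::point_polyline_distance(p, axis)))
  expect_lt(dmax, sqrt(3) * 0.5)
  # identical seeds rejected
  expect_error(extract_bifurcation_centerlines(cv, vox[1, ], vox[2, ],
                                               vox[2, ]), "distinct")
})

test_that("unreachable targets are reported as such", {
  costs <- array(1, c(5, 3, 1))
  costs[3, , 1] <- Inf  # wall across the grid
  cv <- structure(list(costs = costs, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)), class = "cost_volume")
  expect_error(least_cost_path(cv, c(0, 0, 0), c(4, 0, 0)),
               "no finite-cost path")
})
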