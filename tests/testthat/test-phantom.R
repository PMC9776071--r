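test_that("bifurcation geometry honours radii, stenosis and apex", {
  g0 <- make_bifurcation_geometry(phantom_config(stenosis_fraction = 0))
  # no stenosis: ICA radius profile has no dip below the blended baseline
  ica <- g0$branches$ica
  expect_gte(min(ica$r_lumen), min(g0$config$r_ica, g0$config$r_cca))

  g <- make_bifurcation_geometry(phantom_config(stenosis_fraction = 0.81))
  expect_equal(min(g$branches$ica$r_lumen), 2.5 * (1 - 0.81),
               tolerance = 1e-10)

  # apex lies on all three branch axes
  for (b in g$branches)
    expect_lt(plaquescan:::point_polyline_distance(g$apex_point, b$points),
              0.25)

  expect_error(make_bifurcation_geometry(phantom_config(stenosis_fraction = 1)),
               "stenosis_fraction")
  expect_error(make_bifurcation_geometry(phantom_config(ica_angle = 0)),
               "angle")
})

test_that("rasterization recovers analytic inclusion volumes and converges", {
  geom <- straight_tube_geometry()
  # empty plaque: no inclusion voxels
  lab0 <- rasterize_labels(geom, plaque_spec(), grid = 0.4)
  expect_equal(component_volume(lab0, "lipid"), 0)
  expect_equal(component_volume(lab0, "calcification"), 0)

  ell <- list(center = c(0, 3.5, 6), semi_axes = c(1.0, 0.8, 1.5),
              axes = NULL, name = "calc-test")
  v_true <- 4 / 3 * pi * prod(ell$semi_axes)
  err <- sapply(c(0.5, 0.25), function(sp) {
    lab <- rasterize_labels(geom, plaque_spec(calcification = list(ell)),
                            grid = sp)
    abs(component_volume(lab, "calcification") - v_true) / v_true
  })
  expect_lt(err[2], 0.05)     # within 5% of 4/3 pi abc at 0.25 mm
  expect_lt(err[2], err[1])   # halving the spacing reduces the error

  # an inclusion escaping the wall raises a named error
  bad <- list(center = c(0, 1.5, 6), semi_axes = c(1, 1, 1), axes = NULL,
              name = "escapee")
  expect_error(rasterize_labels(geom, plaque_spec(lipid = list(bad)),
                                grid = 0.4),
               "escapee")
})

test_that("contrast rendering is exact at zero noise and seeded", {
  fx <- phantom_fixture(1, spacing = 0.4, noise_sd = 0)
  sig <- default_signatures()
  # piecewise constant at the class means
  for (ch in colnames(sig)) {
    vals <- unique(as.vector(fx$stack$channels[[ch]]))
    expect_true(all(vals %in% sig[, ch]))
  }
  # TOF makes the lumen the brightest class
  expect_equal(unname(which.max(sig[, "TOF"])),
               unname(which(rownames(sig) == "lumen")))
  # determinism: same seed, bit-identical; noise-free invertibility
  s1 <- render_contrasts(fx$labels, noise_sd = 0.03, seed = 11)
  s2 <- render_contrasts(fx$labels, noise_sd = 0.03, seed = 11)
  expect_identical(s1$channels, s2$channels)

  # nearest-signature classification inverts the noise-free rendering
  X <- vapply(names(fx$stack$channels),
              function(ch) as.vector(fx$stack$channels[[ch]]),
              numeric(length(fx$labels$labels)))
  d2 <- plaquescan:::dist2_to_centroids(X, sig[, colnames(X)])
  cls <- tissue_codes[rownames(sig)[max.col(-d2)]]
  expect_equal(unname(cls), as.vector(fx$labels$labels))

  expect_error(render_contrasts(fx$labels, signatures = sig[-2, ]),
               "signature")
})

test_that("rendered per-class sample means match signatures under noise", {
  fx <- phantom_fixture(1, spacing = 0.4, noise_sd = 0.05, seed = 21)
  sig <- default_signatures()
  for (cls in c("lumen", "wall")) {
    sel <- fx$labels$labels == tissue_codes[[cls]]
    n <- sum(sel)
    expect_gt(n, 1000)
    for (ch in names(fx$stack$channels)) {
      se <- 0.05 / sqrt(n)
      expect_lt(abs(mean(fx$stack$channels[[ch]][sel]) - sig[cls, ch]),
                3 * se + 1e-12)
    }
  }
})

test_that("flow waveform meets mean/peak constraints on its grid", {
  w <- make_flow_waveform(period = 1, q_mean = 6, q_peak = 20, n_frames = 40)
  expect_equal(length(w$times), 41)
  expect_equal(unique(round(diff(w$times), 12)), 1 / 40)
  expect_equal(max(w$values), 20)
  expect_lt(abs(pracma::trapz(w$times, w$values) / 1 - 6) / 6, 0.01)
  # a unique global (systolic) maximum in the first half of the cycle; the
  # template's dicrotic bump is a smaller secondary local maximum
  expect_equal(sum(w$values == max(w$values)), 1)
  expect_lt(w$times[which.max(w$values)], 0.5 * w$period)

  # nearly flat limit still meets the mean constraint
  w2 <- make_flow_waveform(1, 6, 6 + 1e-6, 40)
  expect_lt(abs(pracma::trapz(w2$times, w2$values) - 6) / 6, 0.01)

  # seeded shape perturbation is deterministic and keeps the constraints
  w3 <- make_flow_waveform(1, 6, 20, 40, seed = 5)
  w4 <- make_flow_waveform(1, 6, 20, 40, seed = 5)
  expect_identical(w3$values, w4$values)
  expect_equal(max(w3$values), 20)

  expect_error(make_flow_waveform(1, 6, 6, 40), "q_peak")
  expect_error(make_flow_waveform(1, 6, 20, 4), "n_frames")
})

test_that("pressure scaling maps flow range onto [p_dia, p_sys] affinely", {
  flow <- waveform(c(0, 0.25, 0.5, 0.75, 1), c(2, 6, 10, 6, 2), 1)
  p <- scale_pressure_waveform(flow, 80, 120)
  expect_equal(p$values, c(80, 100, 120, 100, 80))
  expect_identical(p$times, flow$times)
  # order preserved on a monotone segment
  expect_true(all(diff(p$values[1:3]) > 0))
  flat <- waveform(c(0, 0.5, 1), c(5, 5, 5), 1)
  expect_error(scale_pressure_waveform(flat, 80, 120), "constant")
})

test_that("waveform CSV round-trips and NIfTI volume IO preserves geometry", {
  w <- make_flow_waveform(1, 6, 20, 40)
  f <- tempfile(fileext = ".csv")
  write_waveform(w, f)
  w2 <- read_waveform(f)
  expect_equal(w2$values, w$values)
  expect_equal(w2$times, w$times)

  fx <- phantom_fixture(1, spacing = 0.4, noise_sd = 0)
  nf <- tempfile(fileext = ".nii.gz")
  write_label_volume(fx$labels, nf)
  lab2 <- read_label_volume(nf)
  expect_equal(lab2$labels, fx$labels$labels, ignore_attr = TRUE)
  expect_equal(lab2$spacing, fx$labels$spacing, tolerance = 1e-6)
  expect_equal(lab2$origin, fx$labels$origin, tolerance = 1e-4)
})
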