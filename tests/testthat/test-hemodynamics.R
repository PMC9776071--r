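# synthetic WSS field with prescribed per-time magnitudes along fixed or
# rotating directions
synthetic_field <- function(times, mags, dirs, period = max(times)) {
  n_t <- length(times)
  tau <- array(0, c(nrow(mags), n_t, 3))
  for (k in seq_len(n_t))
    tau[, k, ] <- mags[, k] * matrix(dirs[k, ], nrow(mags), 3, byrow = TRUE)
  structure(list(points = data.frame(x = 0, y = 0, z = 0,
                                     branch = "ica",
                                     arclength_mm = seq_len(nrow(mags))),
                 times = times, tau = tau, period = period,
                 surrogate = FALSE),
            class = "wss_field")
}

test_that("Poiseuille surrogate reproduces the hand-computed magnitude", {
  # mu = 0.00345 Pa s, Q = 5 mL/s, r = 2.5 mm -> tau = 4 mu Q / (pi r^3)
  geom <- straight_tube_geometry(r = 2.5, h = 1, len = 10)
  flow <- waveform(c(0, 0.5, 1), c(5, 5, 5), 1)
  field <- surrogate_wss_field(geom, flow)
  cca <- field$points$branch == "cca"
  expect_equal(unique(round(sqrt(rowSums(field$tau[cca, 1, ]^2)), 6)),
               round(4 * 0.00345 * 5e-6 / (pi * 2.5e-3^3), 6))
  expect_true(isTRUE(field$surrogate))
})

test_that("surrogate WSS follows the cubic radius law and peaks at the throat", {
  g1 <- straight_tube_geometry(r = 2, h = 1, len = 10)
  g2 <- straight_tube_geometry(r = 1, h = 1, len = 10)
  flow <- waveform(c(0, 0.5, 1), c(5, 6, 5), 1)
  f1 <- surrogate_wss_field(g1, flow)
  f2 <- surrogate_wss_field(g2, flow)
  m1 <- max(sqrt(rowSums(f1$tau[f1$points$branch == "cca", 1, ]^2)))
  m2 <- max(sqrt(rowSums(f2$tau[f2$points$branch == "cca", 1, ]^2)))
  expect_equal(m2 / m1, 8, tolerance = 1e-9)

  fx <- phantom_fixture(1, spacing = 0.4, noise_sd = 0)
  fs <- surrogate_wss_field(fx$geom, make_flow_waveform())
  mags <- sqrt(fs$tau[, , 1]^2 + fs$tau[, , 2]^2 + fs$tau[, , 3]^2)
  throat <- which.min(fs$points$radius_mm)
  for (k in seq_along(fs$times))
    expect_equal(which.max(mags[, k]), throat)
})

test_that("TAWSS quadrature matches closed forms and converges", {
  # constant magnitude c -> TAWSS = c
  t40 <- seq(0, 1, length.out = 41)
  f_const <- synthetic_field(t40, matrix(2.5, 3, 41),
                             matrix(rep(c(1, 0, 0), 41), ncol = 3,
                                    byrow = TRUE))
  expect_equal(tawss(f_const)$values, rep(2.5, 3))
  # A |sin(2 pi t / T)| has cycle mean 2A/pi
  A <- pi
  mag <- matrix(abs(A * sin(2 * pi * t40)), 1, 41, byrow = TRUE)
  f_sin <- synthetic_field(t40, mag,
                           matrix(rep(c(0, 0, 1), 41), ncol = 3,
                                  byrow = TRUE))
  expect_lt(abs(tawss(f_sin)$values[1] - 2 * A / pi) / (2 * A / pi), 0.005)
  # doubling the sampling density changes a smooth integrand < 0.1%
  smooth_mag <- function(t) 2 + sin(2 * pi * t)
  t80 <- seq(0, 1, length.out = 81)
  v40 <- tawss(synthetic_field(t40, matrix(smooth_mag(t40), 1),
                               matrix(rep(c(1, 0, 0), 41), ncol = 3,
                                      byrow = TRUE)))$values
  v80 <- tawss(synthetic_field(t80, matrix(smooth_mag(t80), 1),
                               matrix(rep(c(1, 0, 0), 81), ncol = 3,
                                      byrow = TRUE)))$values
  expect_lt(abs(v80 - v40) / v80, 0.001)
})

test_that("OSI hits its analytic limits and is monotone in steady shear", {
  t <- seq(0, 1, length.out = 41)
  dirs <- matrix(rep(c(1, 0, 0), 41), ncol = 3, byrow = TRUE)
  # unidirectional: OSI 0
  f_uni <- synthetic_field(t, matrix(1 + abs(sin(2 * pi * t)), 1), dirs)
  expect_equal(osi(f_uni)$values[1], 0, tolerance = 1e-9)
  # zero-mean sinusoid along a fixed axis: OSI 0.5
  f_osc <- synthetic_field(t, matrix(sin(2 * pi * t), 1), dirs)
  expect_equal(osi(f_osc)$values[1], 0.5, tolerance = 1e-6)
  # steady offset s decreases OSI monotonically
  osi_of <- function(s) {
    f <- synthetic_field(t, matrix(s + sin(2 * pi * t), 1), dirs)
    osi(f)$values[1]
  }
  vals <- vapply(seq(0, 1.5, by = 0.25), osi_of, 0)
  expect_true(all(diff(vals) < 1e-12))
  expect_true(all(vals >= 0 & vals <= 0.5))
  # all-zero field: masked with a warning
  f0 <- synthetic_field(t, matrix(0, 2, 41), dirs)
  expect_warning(m0 <- osi(f0), "masked")
  expect_true(all(is.na(m0$values)))
})

test_that("TAWSS is 1-homogeneous and OSI scale-invariant", {
  fx <- phantom_fixture(1, spacing = 0.5, noise_sd = 0)
  flow <- make_flow_waveform(seed = 2)
  f <- surrogate_wss_field(fx$geom, flow, ds = 1, n_circ = 8)
  f3 <- f; f3$tau <- 3 * f$tau
  expect_equal(tawss(f3)$values, 3 * tawss(f)$values, tolerance = 1e-12)
  expect_equal(osi(f3)$values, osi(f)$values, tolerance = 1e-12)
})

test_that("peak-systole map picks the flow maximum and dominates the mean", {
  fx <- phantom_fixture(1, spacing = 0.5, noise_sd = 0)
  flow <- make_flow_waveform()
  f <- surrogate_wss_field(fx$geom, flow, ds = 1, n_circ = 8)
  pk <- peak_systole_map(f, flow)
  expect_equal(attr(pk, "t_peak"), flow$times[which.max(flow$values)])
  expect_true(all(pk$values >= tawss(f)$values - 1e-9))
  # tie in flow maxima: earliest chosen
  flat <- waveform(c(0, 0.25, 0.5, 0.75, 1), c(1, 4, 2, 4, 1), 1)
  f2 <- synthetic_field(flat$times, matrix(1:5, 1),
                        matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE))
  pk2 <- peak_systole_map(f2, flat)
  expect_equal(attr(pk2, "t_peak"), 0.25)
})

test_that("ROI statistics use apex-anchored arc lengths", {
  fx <- phantom_fixture(1, spacing = 0.5, noise_sd = 0)
  f <- surrogate_wss_field(fx$geom, make_flow_waveform(), ds = 0.5,
                           n_circ = 8)
  tw <- tawss(f)
  st <- roi_stats(tw, roi_spec("ica", 0, 17))
  sel <- f$points$branch == "ica" & f$points$arclength_mm <= 17
  expect_equal(st$n, sum(sel))
  expect_equal(st$mean, mean(tw$values[sel]))
  # constant map: SD 0
  cmap <- tw; cmap$values <- rep(4, length(tw$values))
  stc <- roi_stats(cmap, roi_spec("ica", 0, 17))
  expect_equal(stc$sd, 0)
  # two-point checks of mean and sd
  tiny <- structure(list(points = data.frame(branch = c("ica", "ica"),
                                             arclength_mm = c(1, 2)),
                         values = c(1, 3), name = "x", units = ""),
                    class = "descriptor_map")
  stt <- roi_stats(tiny, roi_spec("ica", 0, 5))
  expect_equal(stt$mean, 2)
  expect_equal(stt$sd, sqrt(2))
  expect_error(roi_stats(tw, roi_spec("ica", 1000, 5)), "no surface points")
})

test_that("WSS field CSV round-trip preserves descriptor results", {
  fx <- phantom_fixture(1, spacing = 0.5, noise_sd = 0)
  f <- surrogate_wss_field(fx$geom, make_flow_waveform(n_frames = 8),
                           ds = 2, n_circ = 4)
  path <- tempfile(fileext = ".csv")
  write_wss_field(f, path)
  f2 <- read_wss_field(path, period = f$period)
  expect_false(isTRUE(f2$surrogate))
  expect_equal(tawss(f2)$values, tawss(f)$values, tolerance = 1e-9)
  expect_equal(osi(f2)$values, osi(f)$values, tolerance = 1e-9)
})
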