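test_that("Laplace hoop stress matches the hand evaluation and scalings", {
  # p = 100 mmHg, r = 3 mm, h = 1 mm -> sigma = p r / h ~ 40 kPa
  geom <- straight_tube_geometry(r = 3, h = 1, len = 10)
  p100 <- waveform(c(0, 0.5, 1), c(100, 100, 100), 1, units = "mmHg")
  f <- laplace_stress(geom, p100, branches = "cca")
  expect_equal(unique(as.vector(round(f$sigma_kPa, 6))),
               round(100 * 133.322 * 3 / 1 / 1000, 6))
  # doubling h halves sigma; linear in pressure and in r/h
  geom2 <- straight_tube_geometry(r = 3, h = 2, len = 10)
  f2 <- laplace_stress(geom2, p100, branches = "cca")
  expect_equal(mean(f2$sigma_kPa) * 2, mean(f$sigma_kPa), tolerance = 1e-9)
  p200 <- waveform(c(0, 0.5, 1), c(200, 200, 200), 1, units = "mmHg")
  f3 <- laplace_stress(geom, p200, branches = "cca")
  expect_equal(f3$sigma_kPa, 2 * f$sigma_kPa, tolerance = 1e-9)
  # zero pressure -> zero stress
  p0 <- waveform(c(0, 0.5, 1), c(0, 50, 0), 1, units = "mmHg")
  f0 <- laplace_stress(geom, p0, branches = "cca")
  expect_equal(f0$sigma_kPa[, 1], rep(0, length(f0$arclength_mm)))
})

test_that("stress ROI window centres on the peak plane with spec tie rules", {
  # constant stress: mean = max, SD = 0, central plane at the first section
  geom <- straight_tube_geometry(r = 3, h = 1, len = 30)
  p <- waveform(c(0, 0.3, 1), c(80, 120, 80), 1, units = "mmHg")
  f <- laplace_stress(geom, p, branches = "cca")
  st <- suppressWarnings(stress_roi_stats(f, length = 13))
  expect_equal(st$sd, 0)
  expect_equal(st$mean, st$max)
  expect_equal(st$central_s_mm, 0)
  expect_warning(stress_roi_stats(f, length = 80), "truncated")

  # monotone profile: central plane at the domain end (exhaustive argmax)
  f_mono <- f
  f_mono$sigma_kPa <- f$sigma_kPa *
    matrix(seq(1, 2, length.out = length(f$arclength_mm)),
           length(f$arclength_mm), length(f$times))
  st2 <- suppressWarnings(stress_roi_stats(f_mono, length = 13))
  expect_equal(st2$central_s_mm, max(f$arclength_mm))
  prof <- f_mono$sigma_kPa[, f_mono$peak_index]
  expect_equal(which.max(prof), length(prof))

  # window invariance to arc-length offsets
  f_off <- f_mono
  f_off$arclength_mm <- f_mono$arclength_mm + 100
  st3 <- suppressWarnings(stress_roi_stats(f_off, length = 13))
  expect_equal(st3$mean, st2$mean)
  expect_equal(st3$max, st2$max)
})

test_that("default 13 mm window is used and lies inside a long vessel", {
  fx <- phantom_fixture(1, spacing = 0.5, noise_sd = 0)
  p <- scale_pressure_waveform(make_flow_waveform(), 80, 120)
  f <- laplace_stress(fx$geom, p)
  st <- stress_roi_stats(f)
  # sections within +-6.5 mm of the central plane, roughly 13/axis step
  expect_equal(diff(range(f$arclength_mm[f$arclength_mm >=
    st$central_s_mm - 6.5 & f$arclength_mm <= st$central_s_mm + 6.5])),
    13, tolerance = 0.5)
  expect_gte(st$max, st$mean)
})

test_that("pairwise comparisons reproduce printed reference arithmetic", {
  ref <- reference_case_summaries()
  cmp <- compare_patients(ref)
  # calcification fold ratios: 77.38/3.44 and 77.38/10.43
  expect_equal(plaquescan:::comparison_value(cmp, "calcification_volume",
                                             "patient2", "patient1"),
               77.38 / 3.44, tolerance = 1e-12)
  expect_equal(plaquescan:::trunc_digits(
    plaquescan:::comparison_value(cmp, "calcification_volume", "patient2",
                                  "patient1"), 1), 22.4)
  # lipid folds
  expect_equal(plaquescan:::trunc_digits(
    plaquescan:::comparison_value(cmp, "lipid_volume", "patient3",
                                  "patient1"), 1), 5.5)
  expect_equal(round(plaquescan:::comparison_value(cmp, "lipid_volume",
                                                   "patient3", "patient2"),
                     2), 4.87)
  # stress percent differences relative to the smaller-valued case
  expect_equal(plaquescan:::trunc_digits(
    plaquescan:::comparison_value(cmp, "stress_max", "patient1",
                                  "patient2"), 1), 13.8)
  expect_equal(plaquescan:::trunc_digits(
    plaquescan:::comparison_value(cmp, "stress_max", "patient3",
                                  "patient2"), 1), 8.9)
  # antisymmetry of fold ratios
  r_ab <- plaquescan:::comparison_value(cmp, "tawss_mean", "patient2",
                                        "patient1")
  r_ba <- plaquescan:::comparison_value(cmp, "tawss_mean", "patient1",
                                        "patient2")
  expect_equal(r_ab * r_ba, 1, tolerance = 1e-12)
})

test_that("identical cases compare as unity ratios and zero differences", {
  s <- list(a = list(calcification_volume_mm3 = 5, lipid_volume_mm3 = 7,
                     tawss_mean_pa = 2, stress_max_kpa = 100),
            b = list(calcification_volume_mm3 = 5, lipid_volume_mm3 = 7,
                     tawss_mean_pa = 2, stress_max_kpa = 100))
  cmp <- compare_patients(s)
  expect_true(all(cmp$value[cmp$type == "fold"] == 1))
  expect_true(all(cmp$value[cmp$type == "pct_diff"] == 0))
  # zero denominators are undefined, not errors
  s$b$calcification_volume_mm3 <- 0
  cmp2 <- compare_patients(s)
  expect_true(is.na(plaquescan:::comparison_value(
    cmp2, "calcification_volume", "a", "b")))
  expect_error(compare_patients(s["a"]), "two case")
})
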