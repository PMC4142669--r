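test_that("circle-fitting diameter closed forms", {
  expect_equal(circle_fit_diameter(pi), 2.0)
  expect_equal(circle_fit_diameter(4 * pi), 4.0)
  expect_equal(circle_fit_diameter(10), 2 * sqrt(10 / pi))
  expect_equal(circle_fit_diameter(10), 3.5682482, tolerance = 1e-7)
  expect_error(circle_fit_diameter(0), class = "stereofiber_error_measure")
  expect_error(circle_fit_diameter(-3), class = "stereofiber_error_measure")
})

test_that("per-fiber morphometry reproduces the defining formulas", {
  m <- measure_fibers(tibble::tibble(fiber_id = 1, axon_area_um2 = 9 * pi,
                                     fiber_area_um2 = 25 * pi))
  expect_equal(m$d_um, 6); expect_equal(m$D_um, 10)
  expect_equal(m$myelin_um, 2.0)
  expect_equal(m$g_ratio, 0.6)

  inv <- measure_fibers(tibble::tibble(fiber_id = 1, axon_area_um2 = 9 * pi,
                                       fiber_area_um2 = 25 * pi),
                        g_convention = "D_over_d")
  expect_equal(inv$g_ratio, 10 / 6)

  # areas in ratio 4 give diameters in ratio 2, so g = 1/2 exactly
  m2 <- measure_fibers(tibble::tibble(fiber_id = 1, axon_area_um2 = 3,
                                      fiber_area_um2 = 12))
  expect_equal(m2$g_ratio, 0.5)
  expect_equal(m2$d_um, 2 * sqrt(3 / pi))
  expect_equal(m2$myelin_um, sqrt(3 / pi))

  expect_error(measure_fibers(tibble::tibble(fiber_id = 1, axon_area_um2 = 5,
                                             fiber_area_um2 = 5)),
               class = "stereofiber_error_measure")
})

test_that("diameters round-trip through areas and scale equivariantly", {
  set.seed(11)
  d <- runif(200, 0.2, 8); D <- d / runif(200, 0.4, 0.9)
  m <- measure_fibers(tibble::tibble(fiber_id = seq_along(d),
                                     axon_area_um2 = pi * (d / 2)^2,
                                     fiber_area_um2 = pi * (D / 2)^2))
  expect_equal(m$d_um, d, tolerance = 1e-9)
  expect_equal(m$D_um, D, tolerance = 1e-9)

  k <- 3.7
  mk <- measure_fibers(tibble::tibble(fiber_id = seq_along(d),
                                      axon_area_um2 = k^2 * pi * (d / 2)^2,
                                      fiber_area_um2 = k^2 * pi * (D / 2)^2))
  expect_equal(mk$d_um, k * m$d_um, tolerance = 1e-12)
  expect_equal(mk$myelin_um, k * m$myelin_um, tolerance = 1e-12)
  expect_equal(mk$g_ratio, m$g_ratio, tolerance = 1e-12)
})

test_that("measurement summaries are mean and n-1 SD, degenerate cases flagged", {
  one <- measure_fibers(tibble::tibble(fiber_id = 1, axon_area_um2 = pi,
                                       fiber_area_um2 = 4 * pi))
  s1 <- summarize_measurements(one)
  expect_equal(s1$mean[s1$parameter == "d_um"], 2)
  expect_equal(s1$sd, rep(0, 4))
  expect_true(all(s1$sd_degenerate))

  two <- measure_fibers(tibble::tibble(fiber_id = 1:2,
                                       axon_area_um2 = c(pi, pi),
                                       fiber_area_um2 = c(4 * pi, 4 * pi)))
  expect_equal(summarize_measurements(two)$sd, rep(0, 4))
  expect_error(summarize_measurements(one[0, ]), class = "stereofiber_error_measure")

  # generator fibers: measured mean axon diameter matches the mixture moments
  sec <- simulate_section(fiber_phenotype("control", n_fibers = 1000),
                          nerve_radius = 150, seed = 31)
  m <- measure_fibers(fiber_areas(sec))
  main <- lnorm_moments(log(3.5), 0.35); small <- lnorm_moments(log(0.35), 0.2)
  mix <- mixture_moments(0.10, main["mean"], main["var"], small["mean"], small["var"])
  expect_lt(abs(mean(m$d_um) - mix["mean"]), 3 * sqrt(mix["var"] / 1000))
})

test_that("tracing noise perturbs areas but never inverts the geometry", {
  sec <- simulate_section(small_phenotype("control", 80), nerve_radius = 52, seed = 2)
  a0 <- fiber_areas(sec)
  a1 <- fiber_areas(sec, area_noise_sd = 0.05, seed = 9)
  expect_false(isTRUE(all.equal(a0$axon_area_um2, a1$axon_area_um2)))
  expect_true(all(a1$axon_area_um2 < a1$fiber_area_um2))
  expect_identical(a1, fiber_areas(sec, area_noise_sd = 0.05, seed = 9))
})
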