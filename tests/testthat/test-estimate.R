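test_that("density and total-number arithmetic", {
  counts <- tibble::tibble(frame_id = 1:2, n_counted = c(6, 4),
                           frame_area_um2 = c(500, 500))
  expect_equal(estimate_density(counts), 10 / 1000 * 1e6)   # 10 fibers in 0.001 mm2
  expect_equal(estimate_density(dplyr::mutate(counts, n_counted = 0L)), 0)

  em <- tibble::tibble(frame_id = 1, n_counted = 8, frame_area_um2 = 12.2 * 16.2)
  expect_equal(estimate_density(em), 8 / 197.64 * 1e6)
  expect_equal(estimate_density(em), 40477.6, tolerance = 1e-5)

  tot <- estimate_total(20000, 0.05 * 1e6)
  expect_equal(as.numeric(tot), 1000)
  expect_equal(attr(tot, "rounded"), 1000)
  expect_equal(as.numeric(estimate_total(0, 100)), 0)

  expect_error(estimate_density(counts[0, ]), class = "stereofiber_error_estimate")
  expect_error(estimate_total(10, 0), class = "stereofiber_error_estimate")
  expect_error(estimate_total(-1, 10), class = "stereofiber_error_estimate")
})

test_that("ratio of sums equals mean of per-frame ratios for congruent frames", {
  set.seed(5)
  counts <- tibble::tibble(frame_id = 1:12, n_counted = rpois(12, 7),
                           frame_area_um2 = rep(314.159265, 12))
  expect_equal(estimate_density(counts),
               mean(counts$n_counted / counts$frame_area_um2) * 1e6,
               tolerance = 1e-12)
})

test_that("clipped areas drive the density; geometric areas remain available", {
  counts <- tibble::tibble(frame_id = 1:2, n_counted = c(5, 0),
                           frame_area_um2 = c(100, 100),
                           area_in_nerve_um2 = c(100, 0))
  expect_equal(estimate_density(counts), 5 / 100 * 1e6)
  expect_equal(estimate_density(counts, area = "geometric"), 5 / 200 * 1e6)
})

test_that("a tiling of the bounding box recovers the exact count scaled by area ratio", {
  for (s in 1:10) {
    sec <- simulate_section(small_phenotype("control", 50), nerve_radius = 42, seed = s)
    frames <- tile_frames(sec, nx = 4, ny = 3)
    counts <- count_frames(sec, frames, rule = "fiber")
    dens <- estimate_density(counts, area = "geometric")
    tot <- as.numeric(estimate_total(dens, section_area(sec)))
    bbox_area <- sum(frames$area_um2)
    expect_equal(tot, nrow(sec) * section_area(sec) / bbox_area, tolerance = 1e-12)
  }
})

test_that("the total-fiber estimate is invariant under rescaling all lengths", {
  sec <- simulate_section(small_phenotype("control", 40), nerve_radius = 40, seed = 3)
  k <- 2.5
  tb <- section_to_table(sec)
  sec_k <- table_to_section(dplyr::mutate(tb,
                                          x_um = x_um * k, y_um = y_um * k,
                                          axon_diameter_um = axon_diameter_um * k,
                                          fiber_diameter_um = fiber_diameter_um * k),
                            nerve_radius_um = 40 * k)
  frame <- manual_circle_frame(5, -3, 12)
  frame_k <- manual_circle_frame(5 * k, -3 * k, 12 * k)
  c1 <- count_frames(sec, clip_frames_to_nerve(frame, sec))
  c2 <- count_frames(sec_k, clip_frames_to_nerve(frame_k, sec_k))
  expect_equal(c1$n_counted, c2$n_counted)
  t1 <- as.numeric(estimate_total(estimate_density(c1), section_area(sec)))
  t2 <- as.numeric(estimate_total(estimate_density(c2), section_area(sec_k)))
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("estimate_section assembles counts, morphometry and the estimators coherently", {
  sec <- simulate_section(fiber_phenotype("control", n_fibers = 150),
                          nerve_radius = 80, seed = 4)
  est <- estimate_section(sec, sampling_design("LM", n_fields = 10), seed = 2,
                          detection = NULL)
  expect_s3_class(est, "stereology_estimate")
  counts <- est$counts[[1]]
  expect_equal(est$total_counted, sum(counts$n_counted))
  expect_equal(est$density_per_mm2,
               sum(counts$n_counted) / sum(counts$area_in_nerve_um2) * 1e6)
  expect_equal(est$total_fibers, est$density_per_mm2 * est$nerve_area_um2 / 1e6)
  expect_equal(nrow(est$measurements[[1]]),
               dplyr::n_distinct(counted_fibers(counts)$fiber_id))
  expect_named(tidy(est), setdiff(names(est), c("counts", "measurements")))
  # detection reduces what the LM observer counts relative to ground truth
  reg <- simulate_section(fiber_phenotype("regenerated"), seed = 9)
  with_det <- estimate_section(reg, sampling_design("LM"), seed = 5)
  no_det <- estimate_section(reg, sampling_design("LM"), seed = 5, detection = NULL)
  expect_lte(with_det$total_counted, no_det$total_counted)
})
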