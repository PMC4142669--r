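test_that("top points sit atop the chosen profile", {
  fib <- tibble::tibble(fiber_id = 1:2, x_um = c(0, 5), y_um = c(0, -3),
                        axon_diameter_um = c(2, 0.5), fiber_diameter_um = c(4, 1))
  tp <- top_points(fib, "fiber")
  expect_equal(tp$top_x_um, c(0, 5))
  expect_equal(tp$top_y_um, c(2, -2.5))
  ta <- top_points(fib, "axon")
  expect_equal(ta$top_y_um, c(1, -2.75))
})

test_that("circular frames use strict interior inclusion", {
  # tops at distance 0, 4.9, 5.0 and 6 from a frame of radius 5: the
  # boundary point must not be counted
  D <- 1
  sec <- manual_section(x = c(0, 0, 0, 0), y = c(0, 4.9, 5.0, 6) - D / 2,
                        d = rep(0.5, 4), D = rep(D, 4), nerve_radius = 10)
  frame <- manual_circle_frame(0, 0, 5)
  counts <- count_frames(sec, frame, rule = "fiber")
  expect_equal(counts$n_counted, 2)
  expect_equal(counted_fibers(counts)$fiber_id, c(1, 2))
})

test_that("rectangular frames are half-open: low edges in, high edges out", {
  D <- 1
  ys <- c(-2, 2, 0, 0) - D / 2          # tops on bottom/top edges and interior
  xs <- c(0, 0, -3, 3)                  # and on left/right edges
  sec <- manual_section(x = xs, y = ys, d = rep(0.4, 4), D = rep(D, 4),
                        nerve_radius = 10)
  frame <- manual_rect_frame(0, 0, 6, 4)
  ids <- counted_fibers(count_frames(sec, frame, rule = "fiber"))$fiber_id
  expect_equal(ids, c(1, 3))            # y = -2 and x = -3 in; y = 2 and x = 3 out
  expect_equal(count_frames(sec[0, ], frame)$n_counted, 0)
})

test_that("counting agrees with the exhaustive oracle on random sections and frames", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- 30
    d <- runif(n, 0.3, 2); D <- d / runif(n, 0.5, 0.85)
    # random non-validated scatter is fine here: counting does not require
    # packed geometry, only coordinates and diameters
    fib <- tibble::tibble(fiber_id = sample(1000, n), x_um = runif(n, -25, 25),
                          y_um = runif(n, -25, 25),
                          axon_diameter_um = d, fiber_diameter_um = D)
    frames <- dplyr::bind_rows(purrr::map(1:20, function(k) {
      if (runif(1) < 0.5)
        manual_circle_frame(runif(1, -25, 25), runif(1, -25, 25),
                            runif(1, 2, 12), frame_id = k, field_id = k)
      else
        manual_rect_frame(runif(1, -25, 25), runif(1, -25, 25),
                          runif(1, 3, 20), runif(1, 3, 20),
                          frame_id = k, field_id = k)
    }))
    rule <- if (rep %% 2) "fiber" else "axon"
    counts <- count_frames(fib, frames, rule = rule)
    long <- counted_fibers(counts)
    for (k in 1:20) {
      expect_identical(sort(long$fiber_id[long$frame_id == k]),
                       oracle_count_frame(fib, frames[k, ], rule))
    }
    expect_equal(counts$n_counted,
                 vapply(1:20, function(k) sum(long$frame_id == k), 0L))
  }
})

test_that("half-open tiling counts every fiber exactly once", {
  ph <- small_phenotype("control", 40)
  for (s in 1:20) {
    sec <- simulate_section(ph, nerve_radius = 40, seed = s)
    counts <- count_frames(sec, tile_frames(sec, nx = 3, ny = 4), rule = "fiber")
    expect_equal(sum(counts$n_counted), nrow(sec))
    expect_false(anyDuplicated(counted_fibers(counts)$fiber_id) > 0)
  }
})

test_that("disjoint frames never count a fiber twice; overlapping fields are flagged", {
  sec <- simulate_section(small_phenotype("control", 50), nerve_radius = 42, seed = 8)
  des <- sampling_design("LM", n_fields = 4, field_width = 30, field_height = 30,
                         frame_radius = 6)
  frames <- make_frames(place_fields(sec, des, seed = 3), des)
  counts <- count_frames(sec, frames)
  expect_lte(sum(counts$n_counted), nrow(sec))
  expect_length(attr(counts, "multiply_counted"), 0)

  # two identical frames attributed to different fields: every counted fiber
  # is sampled by both, and must be flagged
  f2 <- dplyr::bind_rows(manual_circle_frame(0, 0, 15, frame_id = 1, field_id = 1),
                         manual_circle_frame(0, 0, 15, frame_id = 2, field_id = 2))
  c2 <- count_frames(sec, f2)
  expect_equal(c2$n_counted[1], c2$n_counted[2])
  if (c2$n_counted[1] > 0)
    expect_setequal(attr(c2, "multiply_counted"),
                    unique(counted_fibers(c2)$fiber_id))
})
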