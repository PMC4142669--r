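make_host_section <- function(R = 100) {
  manual_section(0, 0, 2, 4, nerve_radius = R, id = "host")
}

test_that("systematic fields keep grid spacing and intersect the nerve", {
  sec <- make_host_section(100)
  des <- sampling_design("LM", n_fields = 4, field_width = 60, field_height = 60)
  f <- place_fields(sec, des, seed = 21)
  expect_equal(nrow(f), 4)
  sp <- attr(f, "spacing_um")
  d <- as.matrix(dist(cbind(f$center_x_um, f$center_y_um)))
  diag(d) <- Inf
  expect_gte(min(d), sp - 1e-9)
  # every field rectangle intersects the nerve disk
  dx <- pmax(abs(f$center_x_um) - 30, 0); dy <- pmax(abs(f$center_y_um) - 30, 0)
  expect_true(all(dx^2 + dy^2 < 100^2))

  f1 <- place_fields(sec, sampling_design("LM", n_fields = 1), seed = 2)
  expect_equal(nrow(f1), 1)
  expect_identical(place_fields(sec, des, seed = 21), f)   # determinism
})

test_that("counting frames have exact areas and sit wholly inside their fields", {
  sec <- make_host_section(100)
  em <- sampling_design("EM", n_fields = 3)
  fr_em <- make_frames(place_fields(sec, em, seed = 4), em)
  expect_equal(nrow(fr_em), 3)
  expect_equal(fr_em$area_um2, rep(12.2 * 16.2, 3))
  expect_equal(fr_em$area_um2[1], 197.64)

  lm <- sampling_design("LM", n_fields = 5, field_width = 60, field_height = 60,
                        frame_radius = 10)
  fields <- place_fields(sec, lm, seed = 4)
  fr <- make_frames(fields, lm)
  expect_equal(nrow(fr), 10)
  expect_equal(sum(fr$area_um2), 5 * 2 * pi * 100, tolerance = 1e-12)
  per_field <- split(fr, fr$field_id)
  for (pf in per_field) {
    expect_equal(abs(diff(pf$cx_um)), 30)                  # centers w/2 apart
    expect_equal(pf$cy_um[1], pf$cy_um[2])
    fld <- fields[fields$field_id == pf$field_id[1], ]
    expect_true(all(pf$cx_um - pf$radius_um >= fld$center_x_um - 30 - 1e-9))
    expect_true(all(pf$cx_um + pf$radius_um <= fld$center_x_um + 30 + 1e-9))
    # the two circles are disjoint
    expect_gte(abs(diff(pf$cx_um)), 2 * pf$radius_um[1])
  }
})

test_that("frames that cannot fit disjointly raise a design error", {
  sec <- make_host_section(100)
  bad <- sampling_design("LM", n_fields = 2, field_width = 60, field_height = 60,
                         frame_radius = 20)
  expect_error(make_frames(place_fields(sec, bad, seed = 1), bad),
               class = "stereofiber_error_design")
})

test_that("clipped frame areas match Monte-Carlo integration and interior frames keep full area", {
  sec <- make_host_section(50)
  frames <- dplyr::bind_rows(
    manual_circle_frame(0, 0, 8, frame_id = 1),            # interior circle
    manual_circle_frame(47, 0, 8, frame_id = 2),           # circle straddling edge
    manual_rect_frame(0, 10, 12, 16, frame_id = 3),        # interior rectangle
    manual_rect_frame(42, 20, 12, 16, frame_id = 4),       # rectangle straddling edge
    manual_rect_frame(70, 0, 12, 16, frame_id = 5)         # rectangle fully outside
  )
  clipped <- clip_frames_to_nerve(frames, sec)
  expect_equal(clipped$area_in_nerve_um2[1], pi * 64, tolerance = 1e-12)
  expect_equal(clipped$area_in_nerve_um2[3], 12 * 16, tolerance = 1e-12)
  expect_equal(clipped$area_in_nerve_um2[5], 0)

  set.seed(404)
  for (i in c(2, 4)) {
    n_mc <- 4e5
    if (clipped$shape[i] == "circle") {
      th <- runif(n_mc) * 2 * pi; rr <- clipped$radius_um[i] * sqrt(runif(n_mc))
      px <- clipped$cx_um[i] + rr * cos(th); py <- clipped$cy_um[i] + rr * sin(th)
      area_f <- pi * clipped$radius_um[i]^2
    } else {
      px <- clipped$cx_um[i] + (runif(n_mc) - 0.5) * clipped$width_um[i]
      py <- clipped$cy_um[i] + (runif(n_mc) - 0.5) * clipped$height_um[i]
      area_f <- clipped$width_um[i] * clipped$height_um[i]
    }
    phat <- mean(px^2 + py^2 < 50^2)
    mc <- phat * area_f
    se <- sqrt(phat * (1 - phat) / n_mc) * area_f
    expect_lt(abs(clipped$area_in_nerve_um2[i] - mc), 4 * se + 1e-9)
  }
})

test_that("uniform tops are covered by LM frames at the rate the in-nerve frame area implies", {
  # the unbiasedness precondition: over random placements, the probability
  # that a uniform point of the nerve falls inside a counting frame equals
  # the expected in-nerve frame area divided by the nerve area
  sec <- make_host_section(100)
  des <- sampling_design("LM", n_fields = 8, field_width = 60, field_height = 60)
  n_rep <- 400
  hit <- logical(n_rep); cov_frac <- numeric(n_rep)
  set.seed(1)
  tops <- matrix(nrow = n_rep, ncol = 2)
  k <- 0
  while (k < n_rep) {   # uniform points in the nerve disk
    p <- runif(2, -100, 100)
    if (sum(p^2) < 100^2) { k <- k + 1; tops[k, ] <- p }
  }
  for (s in seq_len(n_rep)) {
    fr <- clip_frames_to_nerve(make_frames(place_fields(sec, des, seed = s), des), sec)
    circ <- (tops[s, 1] - fr$cx_um)^2 + (tops[s, 2] - fr$cy_um)^2 < fr$radius_um^2
    hit[s] <- any(circ)
    cov_frac[s] <- sum(fr$area_in_nerve_um2) / section_area(sec)
  }
  p_expected <- mean(cov_frac)
  se <- sqrt(p_expected * (1 - p_expected) / n_rep)
  expect_lt(abs(mean(hit) - p_expected), 4 * se)
})
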