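# Independent brute-force oracles, written from the definitions rather than
# by calling package internals, so counting results can be cross-checked.

# top of a disk profile: the boundary point with maximal y
oracle_top_of <- function(x, y, diameter) {
  list(x = x, y = y + diameter / 2)
}

oracle_inside_circle <- function(px, py, cx, cy, r) {
  sqrt((px - cx)^2 + (py - cy)^2) < r
}

oracle_inside_halfopen_rect <- function(px, py, x0, x1, y0, y1) {
  (px >= x0) && (px < x1) && (py >= y0) && (py < y1)
}

# exhaustive per-fiber inclusion test for one frame row
oracle_count_frame <- function(fibers, frame, rule = "fiber") {
  hit <- integer(0)
  for (i in seq_len(nrow(fibers))) {
    diam <- if (rule == "fiber") fibers$fiber_diameter_um[i] else fibers$axon_diameter_um[i]
    tp <- oracle_top_of(fibers$x_um[i], fibers$y_um[i], diam)
    inside <- if (frame$shape == "circle") {
      oracle_inside_circle(tp$x, tp$y, frame$cx_um, frame$cy_um, frame$radius_um)
    } else {
      oracle_inside_halfopen_rect(tp$x, tp$y,
                                  frame$cx_um - frame$width_um / 2,
                                  frame$cx_um + frame$width_um / 2,
                                  frame$cy_um - frame$height_um / 2,
                                  frame$cy_um + frame$height_um / 2)
    }
    if (inside) hit <- c(hit, fibers$fiber_id[i])
  }
  sort(hit)
}

# build a validated section from explicit fiber geometry
manual_section <- function(x, y, d, D, nerve_radius, id = "manual") {
  table_to_section(
    tibble::tibble(fiber_id = seq_along(x), x_um = x, y_um = y,
                   axon_diameter_um = d, fiber_diameter_um = D),
    nerve_radius_um = nerve_radius, section_id = id
  )
}

# one frame row compatible with count_frames()
manual_circle_frame <- function(cx, cy, r, frame_id = 1L, field_id = 1L) {
  tibble::tibble(frame_id = frame_id, field_id = field_id, shape = "circle",
                 cx_um = cx, cy_um = cy, radius_um = r,
                 width_um = NA_real_, height_um = NA_real_, area_um2 = pi * r^2)
}

manual_rect_frame <- function(cx, cy, w, h, frame_id = 1L, field_id = 1L) {
  tibble::tibble(frame_id = frame_id, field_id = field_id, shape = "rectangle",
                 cx_um = cx, cy_um = cy, radius_um = NA_real_,
                 width_um = w, height_um = h, area_um2 = w * h)
}

# closed-form moments of the generator's axon-diameter mixture, written out
# from lognormal / truncated-normal formulas (independent of dist_mean)
lnorm_moments <- function(meanlog, sdlog) {
  m <- exp(meanlog + sdlog^2 / 2)
  v <- (exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2)
  c(mean = m, var = v)
}

tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, var = v)
}

mixture_moments <- function(f, m1, v1, m2, v2) {
  m1 <- unname(m1); v1 <- unname(v1); m2 <- unname(m2); v2 <- unname(v2)
  m <- (1 - f) * m1 + f * m2
  v <- (1 - f) * (v1 + m1^2) + f * (v2 + m2^2) - m^2
  c(mean = m, var = v)
}

# O(n^2) geometric invariant checks on a section
expect_valid_section <- function(sec) {
  R <- attr(sec, "nerve_radius_um")
  expect_true(all(sec$axon_diameter_um > 0))
  expect_true(all(sec$axon_diameter_um < sec$fiber_diameter_um))
  expect_false(anyDuplicated(sec$fiber_id) > 0)
  expect_lte(max(sqrt(sec$x_um^2 + sec$y_um^2) + sec$fiber_diameter_um / 2),
             R * (1 + 1e-9))
  if (nrow(sec) > 1) {
    d2 <- as.matrix(stats::dist(cbind(sec$x_um, sec$y_um)))
    lim <- outer(sec$fiber_diameter_um, sec$fiber_diameter_um, "+") / 2
    diag(d2) <- Inf
    expect_gte(min(d2 - lim), -1e-9)
  }
  expect_gt(section_area(sec), sum(pi * (sec$fiber_diameter_um / 2)^2))
}

small_phenotype <- function(group, n = 60) {
  fiber_phenotype(group, n_fibers = n)
}
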