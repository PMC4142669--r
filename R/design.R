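#' Define a systematic field-sampling design
#'
#' Describes how microscopy fields are laid over a nerve cross-section and
#' which counting frames sit inside them. Light microscopy (`"LM"`) uses a
#' camera field (default 60 x 60 μm at a 100x oil objective) holding two
#' disjoint circular counting frames; electron microscopy (`"EM"`) uses the
#' live screen at 8000x (12.2 x 16.2 μm) as a single rectangular frame.
#'
#' Defaults: LM takes 15 fields per section (the top of the usual 10-15
#' range, for the most precise count) with 10 μm frame radius; EM takes 100
#' fields, so that the total EM frame area is comparable to (about twice)
#' the LM frame area despite the tiny individual frame.
#'
#' @param modality `"LM"` or `"EM"`.
#' @param n_fields Number of fields to sample per section.
#' @param field_width,field_height Field dimensions in μm.
#' @param frame_radius Radius (μm) of the circular counting frames (LM only).
#' @param frames_per_field 2 circles for LM, 1 rectangle for EM (fixed).
#' @param top_rule Which profile top decides membership: the outer fiber
#'   boundary (`"fiber"`, the visible toluidine-blue profile at LM) or the
#'   axon boundary (`"axon"`, what is identified on the EM live image).
#'   Defaults by modality.
#' @return An object of class `sampling_design`.
#' @examples
#' sampling_design("LM")
#' sampling_design("EM", n_fields = 40)
#' @export
sampling_design <- function(modality = c("LM", "EM"),
                            n_fields = NULL,
                            field_width = NULL,
                            field_height = NULL,
                            frame_radius = 10,
                            frames_per_field = NULL,
                            top_rule = NULL) {
  modality <- match.arg(modality)
  if (modality == "LM") {
    n_fields <- n_fields %||% 15L
    field_width <- field_width %||% 60
    field_height <- field_height %||% 60
    frames_per_field <- frames_per_field %||% 2L
    top_rule <- top_rule %||% "fiber"
    if (frames_per_field != 2L)
      stop_design("LM designs use 2 circular frames per field.")
  } else {
    n_fields <- n_fields %||% 100L
    field_width <- field_width %||% 12.2
    field_height <- field_height %||% 16.2
    frames_per_field <- frames_per_field %||% 1L
    top_rule <- top_rule %||% "axon"
    if (frames_per_field != 1L)
      stop_design("EM designs use the whole field as a single rectangular frame.")
  }
  top_rule <- match.arg(top_rule, c("fiber", "axon"))
  if (!is.numeric(n_fields) || length(n_fields) != 1 || n_fields < 1)
    stop_design("`n_fields` must be a positive integer.")
  if (field_width <= 0 || field_height <= 0)
    stop_design("Field dimensions must be positive.")
  if (modality == "LM" && (!is.numeric(frame_radius) || frame_radius <= 0))
    stop_design("`frame_radius` must be positive for LM designs.")
  structure(
    list(modality = modality, n_fields = as.integer(n_fields),
         field_width = field_width, field_height = field_height,
         frames_per_field = as.integer(frames_per_field),
         frame_radius = if (modality == "LM") frame_radius else NA_real_,
         top_rule = top_rule),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("<sampling_design %s> %d fields of %.1f x %.1f um, %d %s frame(s)/field",
              x$modality, x$n_fields, x$field_width, x$field_height,
              x$frames_per_field, if (x$modality == "LM") "circular" else "rectangular"))
  if (x$modality == "LM") cat(sprintf(", r = %.1f um", x$frame_radius))
  cat(sprintf("; top rule: %s\n", x$top_rule))
  invisible(x)
}

#' Place systematic uniform random fields over a section
#'
#' Lays a regular grid of candidate field centers over the nerve's bounding
#' box, offsets the whole grid by a single uniform-random shift inside one
#' grid cell (the classic systematic-uniform-random design: the first field
#' falls at a random place, every further field at a fixed distance from the
#' previous one), enumerates candidates in serpentine order (rows top to
#' bottom, alternating direction), keeps those whose field rectangle
#' intersects the nerve disk, and returns `n_fields` of them. When the grid
#' yields more intersecting candidates than requested, a systematic
#' subsample in serpentine order from a random start (the fractionator
#' principle) selects the `n_fields` kept, so discarded candidates are
#' spread evenly over the section and every candidate — hence every point
#' of the section — retains the same inclusion probability. This is what
#' makes the number estimator unbiased even conditional on a single fixed
#' section. The grid spacing starts at `sqrt(nerve_area / n_fields)` and is
#' shrunk geometrically in the rare case that fewer than `n_fields`
#' candidates intersect the nerve.
#'
#' @param section A `nerve_section`.
#' @param design A [sampling_design()].
#' @param seed Integer seed for the grid offset.
#' @return A tibble of fields (`field_id`, `center_x_um`, `center_y_um`,
#'   `width_um`, `height_um`) with the grid spacing and offset as attributes.
#' @examples
#' sec <- simulate_section(fiber_phenotype("control", n_fibers = 40),
#'                         nerve_radius = 60, seed = 2)
#' place_fields(sec, sampling_design("LM", n_fields = 4, field_width = 30,
#'                                   field_height = 30), seed = 9)
#' @export
place_fields <- function(section, design, seed = 1L) {
  assert_section(section)
  if (!inherits(design, "sampling_design"))
    stop_design("`design` must be built with sampling_design().")
  R <- attr(section, "nerve_radius_um")
  w <- design$field_width; h <- design$field_height
  if (w >= 2 * R && h >= 2 * R)
    stop_design("Field dimensions must be smaller than the nerve bounding box.")
  set.seed(as.integer(seed))
  u <- runif(2)   # the single uniform random offset, in grid-cell units

  # serpentine-ordered candidates intersecting the nerve at a given spacing
  candidates <- function(spacing) {
    off <- u * spacing
    half_x <- R + w / 2
    half_y <- R + h / 2
    xs <- seq(-half_x + off[1], half_x, by = spacing)
    ys <- seq(-half_y + off[2], half_y, by = spacing)
    ys <- sort(ys, decreasing = TRUE)   # rows top to bottom
    grid <- purrr::map_dfr(seq_along(ys), function(i) {
      x_row <- if (i %% 2 == 1) xs else rev(xs)   # serpentine enumeration
      tibble(center_x_um = x_row, center_y_um = ys[i])
    })
    # field rectangle intersects the nerve disk?
    dx <- pmax(abs(grid$center_x_um) - w / 2, 0)
    dy <- pmax(abs(grid$center_y_um) - h / 2, 0)
    grid[dx^2 + dy^2 < R^2, ]
  }

  n_want <- design$n_fields
  spacing <- sqrt(pi * R^2 / n_want)
  hit <- NULL
  for (try in seq_len(60)) {
    hit <- candidates(spacing)
    if (nrow(hit) >= n_want) break
    spacing <- spacing * 0.9
    if (try == 60)
      stop_design("Could not place the requested number of fields intersecting the nerve.")
  }
  m <- nrow(hit)
  if (m > n_want) {
    # systematic subsample (fractionator principle): take every m/n-th
    # candidate in serpentine order from a random start, so the discarded
    # candidates are spread evenly over the section instead of clustered at
    # its far edge. Every candidate is retained with equal probability,
    # preserving uniform inclusion of every top point.
    k0 <- floor(runif(1) * m)
    idx <- sort((floor(k0 + (seq_len(n_want) - 1) * m / n_want) %% m) + 1)
    hit <- hit[idx, ]
  }
  fields <- tibble(field_id = seq_len(n_want),
                   center_x_um = hit$center_x_um,
                   center_y_um = hit$center_y_um,
                   width_um = w, height_um = h)
  attr(fields, "spacing_um") <- spacing
  attr(fields, "offset_um") <- u * spacing
  attr(fields, "modality") <- design$modality
  attr(fields, "seed") <- as.integer(seed)
  fields
}

#' Build counting frames inside sampled fields
#'
#' LM: two congruent circular frames per field, centers on the field's
#' horizontal midline at +/- width/4 from the field center, so they are
#' congruent, disjoint and wholly inside the field. EM: one rectangular
#' frame coinciding with the field itself.
#'
#' @param fields A field tibble from [place_fields()].
#' @param design The [sampling_design()] used to place them.
#' @return A tibble of frames: `frame_id`, `field_id`, `shape`, `cx_um`,
#'   `cy_um`, `radius_um`, `width_um`, `height_um`, `area_um2`.
#' @examples
#' sec <- simulate_section(fiber_phenotype("control", n_fibers = 40),
#'                         nerve_radius = 60, seed = 2)
#' des <- sampling_design("EM", n_fields = 6)
#' make_frames(place_fields(sec, des, seed = 3), des)
#' @export
make_frames <- function(fields, design) {
  if (!inherits(design, "sampling_design"))
    stop_design("`design` must be built with sampling_design().")
  if (design$modality == "LM") {
    r <- design$frame_radius
    if (2 * r > min(design$field_width, design$field_height) / 2)
      stop_design(sprintf(
        "Frame radius %.1f um too large: two disjoint circles cannot fit in a %.1f x %.1f um field.",
        r, design$field_width, design$field_height))
    frames <- tidyr::crossing(field_id = fields$field_id, side = c(-1, 1)) |>
      dplyr::left_join(fields, by = "field_id") |>
      dplyr::transmute(
        field_id = .data$field_id,
        shape = "circle",
        cx_um = .data$center_x_um + .data$side * .data$width_um / 4,
        cy_um = .data$center_y_um,
        radius_um = r,
        width_um = NA_real_, height_um = NA_real_,
        area_um2 = pi * r^2
      )
  } else {
    frames <- dplyr::transmute(
      fields,
      field_id = .data$field_id,
      shape = "rectangle",
      cx_um = .data$center_x_um, cy_um = .data$center_y_um,
      radius_um = NA_real_,
      width_um = .data$width_um, height_um = .data$height_um,
      area_um2 = .data$width_um * .data$height_um
    )
  }
  frames <- dplyr::mutate(frames, frame_id = dplyr::row_number(), .before = 1)
  frames
}

#' Clip frame areas to the nerve cross-section
#'
#' Adds `area_in_nerve_um2`: the exact area of each counting frame's
#' intersection with the nerve disk (closed-form circle-circle lens for
#' circular frames; exact piecewise integration for rectangle-circle).
#' Frames lying wholly inside the nerve keep their full area. The density
#' estimator divides counts by this tissue area, which is what makes the
#' total-number estimate unbiased when fields overhang the nerve edge.
#'
#' @param frames A frame tibble from [make_frames()].
#' @param section The `nerve_section` the frames sample.
#' @return `frames` with an `area_in_nerve_um2` column.
#' @export
clip_frames_to_nerve <- function(frames, section) {
  assert_section(section)
  R <- attr(section, "nerve_radius_um")
  a <- numeric(nrow(frames))
  for (i in seq_len(nrow(frames))) {
    if (frames$shape[i] == "circle") {
      a[i] <- circle_circle_area(frames$cx_um[i], frames$cy_um[i], frames$radius_um[i],
                                 0, 0, R)
    } else {
      a[i] <- circle_rect_area(0, 0, R,
                               frames$cx_um[i] - frames$width_um[i] / 2,
                               frames$cx_um[i] + frames$width_um[i] / 2,
                               frames$cy_um[i] - frames$height_um[i] / 2,
                               frames$cy_um[i] + frames$height_um[i] / 2)
    }
  }
  dplyr::mutate(frames, area_in_nerve_um2 = a)
}

# Exact intersection area of two disks.
circle_circle_area <- function(x1, y1, r1, x2, y2, r2) {
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  c1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  c2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
  r1^2 * acos(pmin(pmax(c1, -1), 1)) + r2^2 * acos(pmin(pmax(c2, -1), 1)) -
    0.5 * sqrt(pmax((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2), 0))
}

# Exact intersection area of a disk (center cx,cy radius r) with the
# axis-aligned rectangle [x0,x1] x [y0,y1], by piecewise closed-form
# integration of the clipped chord height. Antiderivative of
# sqrt(r^2 - x^2) is (x sqrt(r^2-x^2) + r^2 asin(x/r)) / 2.
circle_rect_area <- function(cx, cy, r, x0, x1, y0, y1) {
  # translate so the circle is at the origin
  x0 <- x0 - cx; x1 <- x1 - cx; y0 <- y0 - cy; y1 <- y1 - cy
  xa <- max(x0, -r); xb <- min(x1, r)
  if (xa >= xb || y0 >= r || y1 <= -r) return(0)
  H <- function(x) (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(pmax(x / r, -1), 1))) / 2
  brk <- c(xa, xb)
  for (yy in c(y0, y1)) {
    if (abs(yy) < r) brk <- c(brk, sqrt(r^2 - yy^2) * c(-1, 1))
  }
  brk <- sort(unique(pmin(pmax(brk, xa), xb)))
  total <- 0
  for (k in seq_len(length(brk) - 1)) {
    a <- brk[k]; b <- brk[k + 1]
    if (b <= a) next
    m <- (a + b) / 2
    hm <- sqrt(max(r^2 - m^2, 0))
    up <- min(y1, hm); lo <- max(y0, -hm)
    if (up <= lo) next
    piece <- 0
    if (y1 <= hm) piece <- piece + y1 * (b - a) else piece <- piece + (H(b) - H(a))
    if (y0 >= -hm) piece <- piece - y0 * (b - a) else piece <- piece + (H(b) - H(a))
    total <- total + piece
  }
  total
}
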