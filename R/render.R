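#' Rasterize a section to a grayscale image
#'
#' Presentation-only rasterization of the vector ground truth: light
#' background, dark myelin annulus, lighter axon lumen — the visual analogue
#' of a toluidine-blue semithin section. All analysis runs on the vector
#' coordinates; the raster is for inspection and figures (write it with
#' `png::writePNG()` if needed).
#'
#' @param section A `nerve_section`.
#' @param pixel_size Pixel edge in μm/px.
#' @param max_pixels Pixel budget; exceeding it raises an error rather than
#'   silently allocating a huge image.
#' @param background,myelin,lumen Gray levels in `[0, 1]`.
#' @return A numeric matrix in `[0, 1]`, rows = image rows (top row first).
#' @examples
#' sec <- simulate_section(fiber_phenotype("control", n_fibers = 30),
#'                         nerve_radius = 40, seed = 1)
#' img <- render_section(sec, pixel_size = 1)
#' dim(img)
#' @export
render_section <- function(section, pixel_size = 0.25, max_pixels = 2e7,
                           background = 0.92, myelin = 0.15, lumen = 0.80) {
  assert_section(section)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop_render("`pixel_size` must be a single positive number (um/px).")
  R <- attr(section, "nerve_radius_um")
  npx <- ceiling(2 * R / pixel_size)
  if (npx^2 > max_pixels)
    stop_render(sprintf("Image of %d x %d px exceeds the pixel budget (%g); increase pixel_size.",
                        npx, npx, max_pixels))
  img <- matrix(background, nrow = npx, ncol = npx)
  # pixel-center coordinates; row 1 is the top of the image (largest y)
  xs <- -R + (seq_len(npx) - 0.5) * pixel_size
  ys <- R - (seq_len(npx) - 0.5) * pixel_size
  for (i in seq_len(nrow(section))) {
    Dr <- section$fiber_diameter_um[i] / 2
    dr <- section$axon_diameter_um[i] / 2
    cx <- section$x_um[i]; cy <- section$y_um[i]
    jx <- which(xs >= cx - Dr - pixel_size & xs <= cx + Dr + pixel_size)
    jy <- which(ys >= cy - Dr - pixel_size & ys <= cy + Dr + pixel_size)
    if (!length(jx) || !length(jy)) next
    d2 <- outer(ys[jy] - cy, xs[jx] - cx, function(a, b) a^2 + b^2)
    block <- img[jy, jx, drop = FALSE]
    block[d2 < Dr^2] <- myelin
    block[d2 < dr^2] <- lumen
    img[jy, jx] <- block
  }
  img
}

circle_poly <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Plot a nerve section, optionally with sampling frames
#'
#' Draws the nerve boundary, each fiber as its myelin annulus, and (when
#' given) the counting frames with counted fibers highlighted.
#'
#' @param object A `nerve_section`.
#' @param frames Optional frame tibble from [make_frames()].
#' @param counts Optional count tibble from [count_frames()]; counted fibers
#'   are filled.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot nerve_section
autoplot.nerve_section <- function(object, frames = NULL, counts = NULL, ...) {
  R <- attr(object, "nerve_radius_um")
  boundary <- circle_poly(0, 0, R, 240)
  fib <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    dplyr::mutate(circle_poly(object$x_um[i], object$y_um[i],
                              object$fiber_diameter_um[i] / 2, 24),
                  fiber_id = object$fiber_id[i])
  })
  counted_ids <- if (!is.null(counts)) unique(counted_fibers(counts)$fiber_id) else integer(0)
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = boundary, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.6, colour = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = attr(object, "section_id")) +
    ggplot2::theme_minimal()
  if (nrow(object)) {
    fib$counted <- fib$fiber_id %in% counted_ids
    p <- p + ggplot2::geom_polygon(
      data = fib,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$fiber_id,
                   fill = .data$counted),
      colour = "grey25", linewidth = 0.15, alpha = 0.7, show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = c(`FALSE` = "grey80", `TRUE` = "gold"))
  }
  if (!is.null(frames)) {
    fr <- purrr::map_dfr(seq_len(nrow(frames)), function(i) {
      poly <- if (frames$shape[i] == "circle") {
        circle_poly(frames$cx_um[i], frames$cy_um[i], frames$radius_um[i], 60)
      } else {
        w2 <- frames$width_um[i] / 2; h2 <- frames$height_um[i] / 2
        tibble(x = frames$cx_um[i] + c(-w2, w2, w2, -w2, -w2),
               y = frames$cy_um[i] + c(-h2, -h2, h2, h2, -h2))
      }
      dplyr::mutate(poly, frame_id = frames$frame_id[i])
    })
    p <- p + ggplot2::geom_path(
      data = fr, ggplot2::aes(x = .data$x, y = .data$y, group = .data$frame_id),
      colour = "red3", linewidth = 0.4)
  }
  p
}

#' Plot estimates across a cohort
#'
#' Bar chart of per-nerve total-fiber estimates (or any column) by group and
#' modality, with the group mean +/- SD overlaid — the standard layout for
#' reporting stereological counts.
#'
#' @param estimates A tibble of stacked [estimate_section()] rows (e.g. from
#'   [run_replicate()]'s `$estimates`).
#' @param value Column to plot (default `total_fibers`).
#' @return A ggplot.
#' @export
plot_estimates <- function(estimates, value = "total_fibers") {
  df <- dplyr::mutate(as_tibble(estimates),
                      cell = paste(.data$group, .data$modality))
  summ <- dplyr::summarise(dplyr::group_by(df, .data$cell),
                           mean = mean(.data[[value]]),
                           sd = ifelse(dplyr::n() > 1, sd(.data[[value]]), 0),
                           .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data[[value]])) +
    ggplot2::geom_col(data = summ, ggplot2::aes(y = .data$mean),
                      fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(data = summ,
                           ggplot2::aes(y = .data$mean,
                                        ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 1.4, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
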