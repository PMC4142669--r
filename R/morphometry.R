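#' Circle-fitting (equivalent) diameter
#'
#' Diameter of the circle whose area equals the measured profile area:
#' `2 * sqrt(area / pi)`. This is the standard way to reduce a traced axon
#' or fiber profile to a single calibre value.
#'
#' @param area Profile area(s) in μm²; must be positive.
#' @return Diameter(s) in μm.
#' @examples
#' circle_fit_diameter(pi)    # 2
#' circle_fit_diameter(4 * pi) # 4
#' @export
circle_fit_diameter <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0))
    stop_measure("`area` must be positive and finite.")
  2 * sqrt(area / pi)
}

#' Per-fiber morphometry from axon and fiber areas
#'
#' Computes, for each counted fiber, the circle-fitting axon diameter `d`,
#' fiber diameter `D`, myelin thickness `(D - d) / 2` and g-ratio. The
#' g-ratio is reported as `d / D` (axon/fiber, the standard convention with
#' support in (0,1)); the inverted ratio is available via `g_convention =
#' "D_over_d"` for comparison with sources that print it the other way.
#'
#' @param measurements A data frame with columns `fiber_id`, `axon_area_um2`,
#'   `fiber_area_um2`. [fiber_areas()] builds one from a `nerve_section`.
#' @param g_convention `"d_over_D"` (default) or `"D_over_d"`.
#' @return A tibble `fiber_id`, `axon_area_um2`, `fiber_area_um2`, `d_um`,
#'   `D_um`, `myelin_um`, `g_ratio`.
#' @examples
#' measure_fibers(tibble::tibble(fiber_id = 1, axon_area_um2 = 9 * pi,
#'                               fiber_area_um2 = 25 * pi))
#' @export
measure_fibers <- function(measurements, g_convention = c("d_over_D", "D_over_d")) {
  g_convention <- match.arg(g_convention)
  req <- c("fiber_id", "axon_area_um2", "fiber_area_um2")
  if (!all(req %in% names(measurements)))
    stop_measure(paste0("`measurements` must have columns ", paste(req, collapse = ", "), "."))
  ax <- measurements$axon_area_um2
  fb <- measurements$fiber_area_um2
  if (any(!is.finite(ax)) || any(!is.finite(fb)) || any(ax <= 0))
    stop_measure("Areas must be positive and finite.")
  if (any(ax >= fb))
    stop_measure("Every axon area must be strictly smaller than its fiber area (myelin thickness must be positive).")
  d <- circle_fit_diameter(ax)
  D <- circle_fit_diameter(fb)
  tibble(
    fiber_id = measurements$fiber_id,
    axon_area_um2 = ax,
    fiber_area_um2 = fb,
    d_um = d,
    D_um = D,
    myelin_um = (D - d) / 2,
    g_ratio = if (g_convention == "d_over_D") d / D else D / d
  )
}

#' Axon and fiber areas of section fibers
#'
#' Derives per-fiber profile areas from the section's diameters (areas are
#' exact, `pi (d/2)^2`, since synthetic profiles are circles). Optional
#' multiplicative lognormal noise emulates manual tracing error.
#'
#' @param section A `nerve_section` or fiber tibble.
#' @param fiber_ids Optional subset of fibers (e.g. the counted ones).
#' @param area_noise_sd SD of lognormal area noise (default 0 = exact).
#' @param seed Seed for the noise draws.
#' @return A tibble `fiber_id`, `axon_area_um2`, `fiber_area_um2`.
#' @export
fiber_areas <- function(section, fiber_ids = NULL, area_noise_sd = 0, seed = NULL) {
  fib <- section
  if (!is.null(fiber_ids)) fib <- fib[fib$fiber_id %in% fiber_ids, ]
  ax <- pi * (fib$axon_diameter_um / 2)^2
  fb <- pi * (fib$fiber_diameter_um / 2)^2
  if (area_noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ax <- ax * rlnorm(length(ax), 0, area_noise_sd)
    fb <- fb * rlnorm(length(fb), 0, area_noise_sd)
    # tracing noise must not invert the axon-within-fiber geometry
    bad <- ax >= fb
    ax[bad] <- fb[bad] * 0.99
  }
  tibble(fiber_id = fib$fiber_id, axon_area_um2 = ax, fiber_area_um2 = fb)
}

#' Summarize size parameters across fibers
#'
#' Mean and sample SD (n - 1 denominator) of axon diameter, fiber diameter,
#' myelin thickness and g-ratio, as reported in "mean +/- SD" tables. With a
#' single fiber the SD is reported as 0 and flagged.
#'
#' @param measurements Output of [measure_fibers()].
#' @return A tibble with one row per parameter: `parameter`, `n`, `mean`, `sd`.
#' @export
summarize_measurements <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0)
    stop_measure("Cannot summarize an empty set of measurements.")
  long <- tidyr::pivot_longer(
    dplyr::select(measurements, "d_um", "D_um", "myelin_um", "g_ratio"),
    dplyr::everything(), names_to = "parameter", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
    .groups = "drop"
  )
  out$sd_degenerate <- out$n < 2
  out[match(c("d_um", "D_um", "myelin_um", "g_ratio"), out$parameter), ]
}
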