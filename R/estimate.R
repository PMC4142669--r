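#' Mean fiber density from frame counts
#'
#' The number-per-area ratio estimator: total fibers counted divided by the
#' total counting-frame area, expressed in fibers/mm² (1 mm² = 10⁶ μm²).
#' Counts from all frames are pooled (ratio of sums); for congruent frames
#' this coincides with the mean of per-frame ratios. When the count tibble
#' carries `area_in_nerve_um2` (frames clipped to the nerve,
#' [clip_frames_to_nerve()]) that tissue area is used, so frames overhanging
#' the nerve edge do not dilute the density.
#'
#' @param counts A count tibble from [count_frames()].
#' @param area `"reference"` (use `area_in_nerve_um2` when available, the
#'   default) or `"geometric"` (always the full frame area).
#' @return Density in fibers/mm².
#' @examples
#' counts <- tibble::tibble(frame_id = 1, n_counted = 8, frame_area_um2 = 12.2 * 16.2)
#' estimate_density(counts)  # 40477.6 fibers/mm2
#' @export
estimate_density <- function(counts, area = c("reference", "geometric")) {
  area <- match.arg(area)
  if (is.null(counts) || nrow(counts) == 0)
    stop_estimate("No counting frames: cannot estimate a density.")
  a <- if (area == "reference" && "area_in_nerve_um2" %in% names(counts))
    counts$area_in_nerve_um2 else counts$frame_area_um2
  total_area <- sum(a)
  if (!is.finite(total_area) || total_area <= 0)
    stop_estimate("Total frame area must be positive.")
  sum(counts$n_counted) / total_area * 1e6
}

#' Total fiber number from density and nerve area
#'
#' Multiplies the mean fiber density by the cross-sectional area of the
#' whole nerve. The estimate is real-valued; a rounded integer is attached
#' as the `"rounded"` attribute for reporting.
#'
#' @param density Fiber density in fibers/mm².
#' @param nerve_area_um2 Whole-nerve cross-sectional area in μm².
#' @return Estimated total number of fibers (unrounded).
#' @examples
#' estimate_total(20000, 0.05 * 1e6)  # 1000 fibers
#' @export
estimate_total <- function(density, nerve_area_um2) {
  if (!is.numeric(density) || length(density) != 1 || density < 0)
    stop_estimate("`density` must be a single non-negative number.")
  if (!is.numeric(nerve_area_um2) || length(nerve_area_um2) != 1 || nerve_area_um2 <= 0)
    stop_estimate("`nerve_area_um2` must be a single positive number.")
  total <- density * nerve_area_um2 / 1e6
  attr(total, "rounded") <- round(total)
  total
}

#' One-shot stereological estimate for a section
#'
#' Runs the whole within-section pipeline for one modality: optional
#' detection filtering, systematic field placement, frame construction and
#' clipping to the nerve, top-rule counting, morphometry of the counted
#' fibers, and the density and total-number estimators.
#'
#' @param section A ground-truth `nerve_section`.
#' @param design A [sampling_design()].
#' @param seed Integer seed for field placement (and soft detection).
#' @param detection A [detection_model()], `NULL` for perfect detection, or
#'   `"auto"` to use the modality default (`detection_model(design$modality)`).
#' @param area_noise_sd Lognormal tracing-noise SD for morphometry areas.
#' @return A one-row `stereology_estimate` tibble: `section_id`, `group`,
#'   `modality`, `n_fields`, `total_counted`, `total_frame_area_um2`,
#'   `density_per_mm2`, `nerve_area_um2`, `total_fibers`, `true_n_fibers`,
#'   and list-columns `counts` (per-frame counts, for variance diagnostics)
#'   and `measurements` (per-counted-fiber morphometry).
#' @examples
#' sec <- simulate_section(fiber_phenotype("control", n_fibers = 150),
#'                         nerve_radius = 80, seed = 4)
#' est <- estimate_section(sec, sampling_design("LM", n_fields = 10), seed = 1)
#' glance(est)
#' @export
estimate_section <- function(section, design, seed = 1L, detection = "auto",
                             area_noise_sd = 0) {
  assert_section(section)
  if (identical(detection, "auto")) detection <- detection_model(design$modality)
  observed <- if (is.null(detection)) section else
    apply_detection(section, detection, seed = derive_seed(seed, 7L))
  fields <- place_fields(observed, design, seed = seed)
  frames <- clip_frames_to_nerve(make_frames(fields, design), observed)
  counts <- count_frames(observed, frames, rule = design$top_rule)
  density <- estimate_density(counts)
  total <- estimate_total(density, section_area(section))
  ids <- unique(counted_fibers(counts)$fiber_id)
  meas <- if (length(ids)) {
    measure_fibers(fiber_areas(observed, fiber_ids = ids,
                               area_noise_sd = area_noise_sd,
                               seed = derive_seed(seed, 11L)))
  } else {
    NULL
  }
  out <- tibble(
    section_id = attr(section, "section_id"),
    group = attr(section, "group") %||% NA_character_,
    modality = design$modality,
    n_fields = design$n_fields,
    total_counted = sum(counts$n_counted),
    total_frame_area_um2 = sum(counts$area_in_nerve_um2 %||% counts$frame_area_um2),
    density_per_mm2 = density,
    nerve_area_um2 = section_area(section),
    total_fibers = as.numeric(total),
    true_n_fibers = nrow(section),
    counts = list(counts),
    measurements = list(meas)
  )
  class(out) <- c("stereology_estimate", class(out))
  out
}

#' @export
#' @method tidy stereology_estimate
tidy.stereology_estimate <- function(x, ...) {
  out <- dplyr::select(as_tibble(x), -dplyr::any_of(c("counts", "measurements")))
  as_tibble(out)
}

#' @export
#' @method glance stereology_estimate
glance.stereology_estimate <- function(x, ...) {
  dplyr::select(as_tibble(x), "section_id", "modality", "total_counted",
                "density_per_mm2", "total_fibers", "true_n_fibers")
}
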