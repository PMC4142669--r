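#' Modality-dependent fiber detection model
#'
#' Light microscopy cannot resolve the thinnest myelinated fibers, so an
#' observer counting a toluidine-blue section systematically misses part of
#' the small-calibre tail that electron microscopy still shows. The model is
#' a hard threshold on diameter (default: fibers whose axon diameter is
#' below 0.5 μm — roughly the diffraction scale of light optics — are
#' invisible at LM; EM sees everything), optionally softened to a logistic
#' detection-probability curve.
#'
#' @param modality `"LM"` or `"EM"`.
#' @param min_diameter Hard detection threshold in μm (default 0.5 for LM,
#'   0 for EM).
#' @param diameter Which diameter the threshold applies to: the `"axon"`
#'   diameter (default — what the observer must resolve to identify a
#'   myelinated profile) or the outer `"fiber"` diameter.
#' @param soft_midpoint,soft_slope If both given, detection is stochastic
#'   with probability `plogis(soft_slope * (diam - soft_midpoint))` instead
#'   of the hard threshold.
#' @return An object of class `detection_model`.
#' @examples
#' detection_model("LM")
#' detection_model("LM", soft_midpoint = 0.5, soft_slope = 10)
#' @export
detection_model <- function(modality = c("LM", "EM"),
                            min_diameter = NULL,
                            diameter = c("axon", "fiber"),
                            soft_midpoint = NULL,
                            soft_slope = NULL) {
  modality <- match.arg(modality)
  diameter <- match.arg(diameter)
  min_diameter <- min_diameter %||% if (modality == "LM") 0.5 else 0
  if (!is.numeric(min_diameter) || length(min_diameter) != 1 || min_diameter < 0)
    stop_config("`min_diameter` must be a single non-negative number (um).")
  soft <- !is.null(soft_midpoint) || !is.null(soft_slope)
  if (soft && (is.null(soft_midpoint) || is.null(soft_slope) || soft_slope < 0))
    stop_config("A soft model needs both `soft_midpoint` and a non-negative `soft_slope`.")
  structure(
    list(modality = modality, min_diameter = min_diameter, diameter = diameter,
         soft = soft, soft_midpoint = soft_midpoint, soft_slope = soft_slope),
    class = "detection_model"
  )
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model %s> %s\n", x$modality,
              if (x$soft)
                sprintf("logistic on %s diameter: midpoint %.3g um, slope %.3g", x$diameter, x$soft_midpoint, x$soft_slope)
              else
                sprintf("hard threshold: %s diameter >= %.3g um", x$diameter, x$min_diameter)))
  invisible(x)
}

#' Apply a detection model to a section
#'
#' Returns the sub-section an observer of the given modality would actually
#' see; the ground-truth section is untouched, and section metadata (id,
#' nerve radius, cross-sectional area) is preserved, since the whole-nerve
#' area measurement does not depend on resolving individual small fibers.
#' Detection is applied before field sampling: the observer never counts a
#' fiber they cannot see.
#'
#' @param section A `nerve_section`.
#' @param model A [detection_model()].
#' @param seed Seed for the stochastic (soft) model; ignored by the hard model.
#' @return A `nerve_section` containing the detected fibers.
#' @examples
#' sec <- simulate_section(fiber_phenotype("regenerated", n_fibers = 80),
#'                         nerve_radius = 60, seed = 3)
#' nrow(apply_detection(sec, detection_model("LM")))
#' nrow(apply_detection(sec, detection_model("EM")))
#' @export
apply_detection <- function(section, model, seed = NULL) {
  assert_section(section)
  if (!inherits(model, "detection_model"))
    stop_config("`model` must be built with detection_model().")
  diam <- if (model$diameter == "fiber") section$fiber_diameter_um else section$axon_diameter_um
  if (model$soft) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    p <- stats::plogis(model$soft_slope * (diam - model$soft_midpoint))
    keep <- runif(nrow(section)) < p
  } else {
    keep <- diam >= model$min_diameter
  }
  out <- section[keep, ]
  # subsetting keeps the tibble class but we restore section attributes explicitly
  new_nerve_section(out,
                    section_id = attr(section, "section_id"),
                    nerve_radius_um = attr(section, "nerve_radius_um"),
                    group = attr(section, "group"),
                    seed = attr(section, "seed"),
                    cross_sectional_area_um2 = attr(section, "cross_sectional_area_um2"))
}
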