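#' Fiber-population phenotype parameters
#'
#' Bundles the distributions that define a myelinated-fiber population for
#' the synthetic section generator: the axon-diameter distribution of the
#' main (resolvable) component, the g-ratio distribution, the target fiber
#' count, and a small-calibre mixture component emulating the sub-resolution
#' tail of very thin fibers that only electron microscopy resolves.
#'
#' The built-in defaults describe two phenotypes of mouse median nerve:
#'
#' * `"control"` — uninjured nerve: axon diameter lognormal(median 3.5 μm,
#'   σ_log 0.35); g-ratio truncated Normal(0.65, 0.05) on (0.40, 0.85);
#'   10% of fibers from the small-calibre tail.
#' * `"regenerated"` — 25 days after crush injury: smaller axons
#'   (lognormal median 2.2 μm, σ_log 0.35) with thinner myelin relative to
#'   calibre (g truncated Normal(0.75, 0.05) on (0.50, 0.90)) and a larger
#'   small-fiber tail (20%), reflecting ongoing remyelination.
#'
#' Both phenotypes share the small-fiber axon-diameter distribution
#' (lognormal median 0.35 μm, σ_log 0.2) and a target count of 1200 fibers
#' per section. All values are configurable simulation defaults, not
#' measurements.
#'
#' @param group `"control"` or `"regenerated"`.
#' @param axon_diameter A [stereo_dist] for the main-component axon diameter (μm).
#' @param g_ratio A [stereo_dist] for the g-ratio (axon/fiber diameter), support in (0,1).
#' @param n_fibers Target number of fibers per section.
#' @param small_fraction Proportion in `[0,1]` of fibers drawn from the
#'   small-calibre (sub-resolution) component.
#' @param small_axon_diameter A [stereo_dist] for the small-component axon diameter (μm).
#' @return An object of class `fiber_phenotype`.
#' @examples
#' fiber_phenotype("regenerated")
#' fiber_phenotype("control", n_fibers = 300)
#' @export
fiber_phenotype <- function(group = c("control", "regenerated"),
                            axon_diameter = NULL,
                            g_ratio = NULL,
                            n_fibers = 1200,
                            small_fraction = NULL,
                            small_axon_diameter = dist_lognormal(0.35, 0.2)) {
  group <- match.arg(group)
  defaults <- if (group == "control") {
    list(axon = dist_lognormal(3.5, 0.35),
         g    = dist_truncnorm(0.65, 0.05, 0.40, 0.85),
         small_frac = 0.10)
  } else {
    list(axon = dist_lognormal(2.2, 0.35),
         g    = dist_truncnorm(0.75, 0.05, 0.50, 0.90),
         small_frac = 0.20)
  }
  axon_diameter  <- assert_dist(axon_diameter %||% defaults$axon, "axon_diameter")
  g_ratio        <- assert_dist(g_ratio %||% defaults$g, "g_ratio")
  small_fraction <- small_fraction %||% defaults$small_frac
  assert_dist(small_axon_diameter, "small_axon_diameter")
  if (!is.numeric(n_fibers) || length(n_fibers) != 1 || n_fibers < 0 ||
      n_fibers != round(n_fibers))
    stop_config("`n_fibers` must be a single non-negative integer.")
  if (!is.numeric(small_fraction) || length(small_fraction) != 1 ||
      small_fraction < 0 || small_fraction > 1)
    stop_config("`small_fraction` must be a proportion in [0, 1].")
  structure(
    list(group = group,
         axon_diameter = axon_diameter,
         g_ratio = g_ratio,
         n_fibers = as.integer(n_fibers),
         small_fraction = small_fraction,
         small_axon_diameter = small_axon_diameter),
    class = "fiber_phenotype"
  )
}

#' @export
print.fiber_phenotype <- function(x, ...) {
  cat("<fiber_phenotype '", x$group, "'>\n", sep = "")
  cat("  n_fibers:       ", x$n_fibers, "\n")
  cat("  axon diameter:  "); print(x$axon_diameter)
  cat("  g-ratio:        "); print(x$g_ratio)
  cat("  small fraction: ", x$small_fraction, " from "); print(x$small_axon_diameter)
  invisible(x)
}

# Rescale the length-valued distributions of a phenotype by a multiplier
# (animal-level size effect); the dimensionless g-ratio is untouched.
scale_phenotype <- function(ph, mult) {
  ph$axon_diameter       <- scale_dist(ph$axon_diameter, mult)
  ph$small_axon_diameter <- scale_dist(ph$small_axon_diameter, mult)
  ph
}

scale_dist <- function(dist, mult) {
  switch(dist$family,
    lognormal  = { dist$meanlog <- dist$meanlog + log(mult); dist },
    degenerate = { dist$value <- dist$value * mult; dist },
    truncnorm  = {
      dist$mean <- dist$mean * mult; dist$sd <- dist$sd * mult
      dist$lower <- dist$lower * mult; dist$upper <- dist$upper * mult
      dist
    }
  )
}
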