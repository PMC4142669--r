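#' Configuration for a full synthetic experiment
#'
#' Collects every tunable of the end-to-end replicate: cohort structure,
#' phenotypes, sampling designs and detection models for both modalities.
#' All stage seeds derive deterministically from the single master seed.
#'
#' @param n_animals Animals per cohort (each contributes a control and a
#'   regenerated nerve).
#' @param control,regenerated [fiber_phenotype()]s.
#' @param nerve_radius Baseline nerve radius (μm).
#' @param animal_size_sd,count_cv Cohort variability, see [simulate_cohort()].
#' @param lm_design,em_design [sampling_design()]s per modality.
#' @param lm_detection,em_detection [detection_model()]s per modality.
#' @param area_noise_sd Morphometry tracing-noise SD (default 0).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_animals = 5,
                            control = fiber_phenotype("control"),
                            regenerated = fiber_phenotype("regenerated"),
                            nerve_radius = 160,
                            animal_size_sd = 0.05,
                            count_cv = 0.12,
                            lm_design = sampling_design("LM"),
                            em_design = sampling_design("EM"),
                            lm_detection = detection_model("LM"),
                            em_detection = detection_model("EM"),
                            area_noise_sd = 0,
                            seed = 1L) {
  if (!is.numeric(n_animals) || length(n_animals) != 1 || n_animals < 1)
    stop_config("`n_animals` must be a positive integer.")
  structure(
    list(n_animals = as.integer(n_animals), control = control,
         regenerated = regenerated, nerve_radius = nerve_radius,
         animal_size_sd = animal_size_sd, count_cv = count_cv,
         lm_design = lm_design, em_design = em_design,
         lm_detection = lm_detection, em_detection = em_detection,
         area_noise_sd = area_noise_sd, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic experiment end to end
#'
#' Generates a paired cohort (control and regenerated nerve per animal),
#' applies each modality's detection model, samples fields, counts by the
#' top rule, measures the counted fibers, estimates density and total fiber
#' number per nerve and modality, and runs the paired comparisons a
#' crush-injury study reports:
#'
#' * control vs crush total fiber number, per modality;
#' * control vs crush per-nerve mean axon diameter, fiber diameter, myelin
#'   thickness and g-ratio (LM morphometry);
#' * LM vs EM total fiber number, per group.
#'
#' Deterministic given the config's master seed. If `out_dir` is given, the
#' per-section fiber tables, estimates, comparisons and a JSON manifest are
#' written there as plain CSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list with `cohort` (sections), `estimates` (one row per nerve x
#'   modality), `comparisons` (tidy paired-test rows) and `manifest`.
#' @examples
#' cfg <- pipeline_config(
#'   n_animals = 3,
#'   control = fiber_phenotype("control", n_fibers = 80),
#'   regenerated = fiber_phenotype("regenerated", n_fibers = 80),
#'   nerve_radius = 60,
#'   lm_design = sampling_design("LM", n_fields = 10, field_width = 30,
#'                               field_height = 30, frame_radius = 6),
#'   em_design = sampling_design("EM", n_fields = 30),
#'   seed = 42)
#' res <- run_replicate(cfg)
#' res$comparisons[, c("comparison", "t", "p_value", "tier")]
#' @export
run_replicate <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_config("`config` must be built with pipeline_config().")
  cohort <- simulate_cohort(
    n_animals = config$n_animals, seed = derive_seed(config$seed, 1L),
    control = config$control, regenerated = config$regenerated,
    nerve_radius = config$nerve_radius,
    animal_size_sd = config$animal_size_sd, count_cv = config$count_cv
  )
  designs <- list(LM = config$lm_design, EM = config$em_design)
  detections <- list(LM = config$lm_detection, EM = config$em_detection)
  estimates <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    purrr::map_dfr(names(designs), function(mod) {
      est <- estimate_section(
        cohort$section[[i]], designs[[mod]],
        seed = derive_seed(config$seed, 500L + 10L * i + match(mod, names(designs))),
        detection = detections[[mod]],
        area_noise_sd = config$area_noise_sd
      )
      dplyr::mutate(est, animal = cohort$animal[i], .before = 1)
    })
  })

  comparisons <- replicate_comparisons(estimates)

  manifest <- list(
    n_animals = config$n_animals,
    groups = c("control", "regenerated"),
    modalities = names(designs),
    n_estimates = nrow(estimates),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("stereofiber"))
  )
  result <- list(cohort = cohort, estimates = estimates,
                 comparisons = comparisons, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort)))
      write_fiber_table(cohort$section[[i]],
                        file.path(out_dir, paste0(attr(cohort$section[[i]], "section_id"), ".csv")))
    readr::write_csv(tidy_estimates(estimates), file.path(out_dir, "estimates.csv"))
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

tidy_estimates <- function(estimates) {
  dplyr::select(as_tibble(estimates), -dplyr::any_of(c("counts", "measurements")))
}

# The standard paired contrasts of a crush-injury study, from a stacked
# estimate table.
replicate_comparisons <- function(estimates) {
  est <- as_tibble(estimates)
  out <- list()
  cmp_row <- function(label, a, b, la, lb) {
    row <- tidy(paired_t_test(a, b, la, lb))
    row$comparison <- label
    row
  }

  for (mod in unique(est$modality)) {
    sub <- dplyr::arrange(dplyr::filter(est, .data$modality == mod), .data$animal)
    out[[length(out) + 1]] <- cmp_row(
      paste0("total_fibers_", mod, ": control vs crush"),
      dplyr::filter(sub, .data$group == "control")$total_fibers,
      dplyr::filter(sub, .data$group == "regenerated")$total_fibers,
      "control", "crush")
  }

  for (grp in unique(est$group)) {
    sub <- dplyr::arrange(dplyr::filter(est, .data$group == grp), .data$animal)
    out[[length(out) + 1]] <- cmp_row(
      paste0("total_fibers_", grp, ": LM vs EM"),
      dplyr::filter(sub, .data$modality == "LM")$total_fibers,
      dplyr::filter(sub, .data$modality == "EM")$total_fibers,
      "LM", "EM")
  }

  lm <- dplyr::arrange(dplyr::filter(est, .data$modality == "LM"), .data$animal)
  size_means <- purrr::map_dfr(seq_len(nrow(lm)), function(i) {
    s <- summarize_measurements(lm$measurements[[i]])
    tibble(animal = lm$animal[i], group = lm$group[i],
           parameter = s$parameter, mean = s$mean)
  })
  for (par in c("d_um", "D_um", "myelin_um", "g_ratio")) {
    sub <- dplyr::arrange(dplyr::filter(size_means, .data$parameter == par), .data$animal)
    out[[length(out) + 1]] <- cmp_row(
      paste0(par, "_LM: control vs crush"),
      dplyr::filter(sub, .data$group == "control")$mean,
      dplyr::filter(sub, .data$group == "regenerated")$mean,
      "control", "crush")
  }
  dplyr::bind_rows(out)
}
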