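#' Simulate a ground-truth nerve cross-section
#'
#' Generates a roughly circular transverse nerve section densely packed with
#' non-overlapping myelinated fibers, each modelled as two concentric disks
#' (axon inside myelin). Axon diameters and g-ratios are drawn from the
#' phenotype's distributions (with a small-calibre mixture component), fiber
#' diameters follow as `D = d / g`, and centers are placed by random
#' sequential adsorption: fibers sorted by decreasing diameter, candidate
#' centers uniform inside the region keeping the fiber wholly within the
#' nerve, candidates overlapping an already-placed fiber rejected.
#'
#' Coordinates are continuous Cartesian μm with the origin at the nerve
#' center and y increasing upward.
#'
#' @param phenotype A [fiber_phenotype()]; defaults to `"control"`.
#' @param nerve_radius Nerve boundary radius in μm. The default (160 μm)
#'   puts the default control population at a packing fraction of about 0.40,
#'   where sequential adsorption reliably places every fiber.
#' @param seed Integer seed; the section is bitwise-reproducible given
#'   (`phenotype`, `nerve_radius`, `seed`).
#' @param packing_limit Maximum allowed ratio of total fiber-disk area to
#'   nerve area before attempting placement (default 0.55).
#' @param max_attempts Placement attempts per fiber before failing (default 10000).
#' @param section_id Optional section label.
#' @return A `nerve_section`: a tibble with one row per fiber and columns
#'   `fiber_id`, `x_um`, `y_um`, `axon_diameter_um`, `fiber_diameter_um`,
#'   plus attributes `section_id`, `nerve_radius_um`,
#'   `cross_sectional_area_um2`, `group` and `seed` (see [section_meta()]).
#' @examples
#' sec <- simulate_section(fiber_phenotype("control", n_fibers = 50),
#'                         nerve_radius = 60, seed = 1)
#' sec
#' section_meta(sec)
#' @seealso [simulate_cohort()], [section_to_table()], [apply_detection()]
#' @export
simulate_section <- function(phenotype = fiber_phenotype("control"),
                             nerve_radius = 160,
                             seed = 1L,
                             packing_limit = 0.55,
                             max_attempts = 10000L,
                             section_id = NULL) {
  if (!inherits(phenotype, "fiber_phenotype"))
    stop_config("`phenotype` must be built with fiber_phenotype().")
  if (!is.numeric(nerve_radius) || length(nerve_radius) != 1 || nerve_radius <= 0)
    stop_config("`nerve_radius` must be a single positive number (um).")
  set.seed(as.integer(seed))
  n <- phenotype$n_fibers

  d <- g <- numeric(0)
  if (n > 0) {
    from_small <- runif(n) < phenotype$small_fraction
    d <- numeric(n)
    d[!from_small] <- draw_dist(phenotype$axon_diameter, sum(!from_small))
    d[from_small]  <- draw_dist(phenotype$small_axon_diameter, sum(from_small))
    g <- draw_dist(phenotype$g_ratio, n)
    # rejection-resample draws violating the physical support
    for (iter in seq_len(1000)) {
      bad <- !(d > 0 & g > 0 & g < 1)
      if (!any(bad)) break
      nb <- sum(bad)
      db <- numeric(nb)
      small_b <- from_small[bad]
      db[!small_b] <- draw_dist(phenotype$axon_diameter, sum(!small_b))
      db[small_b]  <- draw_dist(phenotype$small_axon_diameter, sum(small_b))
      d[bad] <- db
      g[bad] <- draw_dist(phenotype$g_ratio, nb)
      if (iter == 1000)
        stop_distribution("Distribution repeatedly produced axon diameters <= 0 or g-ratios outside (0,1).")
    }
  }
  D <- d / g

  nerve_area <- pi * nerve_radius^2
  if (sum(pi * (D / 2)^2) >= packing_limit * nerve_area)
    stop_packing(sprintf(
      "Total fiber area %.0f um^2 exceeds packing limit %.2f x nerve area (%.0f um^2); enlarge the nerve or reduce/shrink fibers.",
      sum(pi * (D / 2)^2), packing_limit, nerve_area))

  ord <- order(D, decreasing = TRUE)
  centers <- tryCatch(
    rsa_pack_disks(D[ord] / 2, nerve_radius, as.integer(max_attempts)),
    error = function(e) {
      if (grepl("^packing:", conditionMessage(e)))
        stop_packing(conditionMessage(e))
      stop(e)
    }
  )
  # restore original draw order so fiber_id is independent of placement order
  inv <- order(ord)
  fibers <- tibble(
    fiber_id = seq_len(n),
    x_um = centers[inv, 1][seq_len(n)],
    y_um = centers[inv, 2][seq_len(n)],
    axon_diameter_um = d,
    fiber_diameter_um = D
  )
  if (n == 0) {
    fibers <- tibble(fiber_id = integer(), x_um = double(), y_um = double(),
                     axon_diameter_um = double(), fiber_diameter_um = double())
  }
  new_nerve_section(fibers,
                    section_id = section_id %||% sprintf("%s_seed%d", phenotype$group, as.integer(seed)),
                    nerve_radius_um = nerve_radius,
                    group = phenotype$group,
                    seed = as.integer(seed))
}

new_nerve_section <- function(fibers, section_id, nerve_radius_um, group = NA_character_,
                              seed = NA_integer_, cross_sectional_area_um2 = NULL) {
  out <- as_tibble(fibers)
  class(out) <- c("nerve_section", class(out))
  attr(out, "section_id") <- section_id
  attr(out, "nerve_radius_um") <- nerve_radius_um
  attr(out, "cross_sectional_area_um2") <- cross_sectional_area_um2 %||% (pi * nerve_radius_um^2)
  attr(out, "group") <- group
  attr(out, "seed") <- seed
  out
}

#' Section metadata
#'
#' @param section A `nerve_section`.
#' @return A one-row tibble with `section_id`, `nerve_radius_um`,
#'   `cross_sectional_area_um2`, `group`, `seed` and `n_fibers`.
#' @export
section_meta <- function(section) {
  assert_section(section)
  tibble(
    section_id = attr(section, "section_id"),
    nerve_radius_um = attr(section, "nerve_radius_um"),
    cross_sectional_area_um2 = attr(section, "cross_sectional_area_um2"),
    group = attr(section, "group") %||% NA_character_,
    seed = attr(section, "seed") %||% NA_integer_,
    n_fibers = nrow(section)
  )
}

#' @rdname section_meta
#' @export
section_area <- function(section) {
  assert_section(section)
  attr(section, "cross_sectional_area_um2")
}

assert_section <- function(section) {
  if (!inherits(section, "nerve_section"))
    stop_config("Expected a `nerve_section` (see simulate_section() or table_to_section()).")
  invisible(section)
}

#' @export
print.nerve_section <- function(x, ...) {
  m <- section_meta(x)
  cat(sprintf("<nerve_section '%s'> %d fibers, nerve radius %.1f um, area %.0f um^2\n",
              m$section_id, m$n_fibers, m$nerve_radius_um, m$cross_sectional_area_um2))
  NextMethod()
}

#' Simulate a paired cohort of control and regenerated nerves
#'
#' Emulates the paired design of a crush-injury experiment: each animal
#' contributes an uninjured (control) nerve and a regenerated (crush) nerve.
#' Animals share a lognormal size multiplier applied to all fiber calibres
#' and to the nerve radius (so larger animals have larger nerves with larger
#' fibers), and each nerve's true fiber count is drawn with a lognormal
#' between-nerve coefficient of variation around the phenotype target —
#' biological count variability without which every synthetic nerve would
#' carry an identical fiber complement. Because fiber number and nerve
#' calibre co-vary anatomically (endoneurial packing density is roughly
#' conserved), a nerve's radius additionally scales with the square root of
#' its count multiplier, keeping the packing fraction at its baseline.
#'
#' @param n_animals Number of animals (default 5).
#' @param seed Master seed; all animal- and nerve-level draws derive from it.
#' @param control,regenerated The two [fiber_phenotype()]s.
#' @param nerve_radius Baseline nerve radius (μm) before the animal multiplier.
#' @param animal_size_sd SD of the animal-level log size multiplier (default 0.05).
#' @param count_cv Between-nerve coefficient of variation of the true fiber
#'   count (default 0.12); 0 fixes every count at the phenotype target.
#' @return A tibble with columns `animal`, `group`, `true_n_fibers` and a
#'   list-column `section` of `nerve_section` objects (2 rows per animal).
#' @examples
#' coh <- simulate_cohort(n_animals = 2, seed = 7,
#'                        control = fiber_phenotype("control", n_fibers = 60),
#'                        regenerated = fiber_phenotype("regenerated", n_fibers = 60),
#'                        nerve_radius = 60)
#' coh
#' @export
simulate_cohort <- function(n_animals = 5,
                            seed = 1L,
                            control = fiber_phenotype("control"),
                            regenerated = fiber_phenotype("regenerated"),
                            nerve_radius = 160,
                            animal_size_sd = 0.05,
                            count_cv = 0.12) {
  if (!is.numeric(n_animals) || length(n_animals) != 1 || n_animals < 1)
    stop_config("`n_animals` must be a positive integer.")
  n_animals <- as.integer(n_animals)
  set.seed(derive_seed(seed, 1L))
  mult <- exp(rnorm(n_animals, 0, animal_size_sd))
  sdlog_count <- sqrt(log(1 + count_cv^2))
  count_mult <- matrix(exp(rnorm(2L * n_animals, 0, sdlog_count)), nrow = n_animals)

  rows <- purrr::map(seq_len(n_animals), function(a) {
    phs <- list(control = control, regenerated = regenerated)
    purrr::imap(phs, function(ph, grp) {
      k <- if (grp == "control") 1L else 2L
      ph <- scale_phenotype(ph, mult[a])
      ph$n_fibers <- max(1L, as.integer(round(ph$n_fibers * count_mult[a, k])))
      sec <- simulate_section(
        ph, nerve_radius = nerve_radius * mult[a] * sqrt(count_mult[a, k]),
        seed = derive_seed(seed, 100L + 10L * a + k),
        section_id = sprintf("animal%02d_%s", a, grp)
      )
      tibble(animal = a, group = grp, true_n_fibers = nrow(sec), section = list(sec))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
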