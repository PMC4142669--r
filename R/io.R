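#' Convert a section to a plain fiber table and back
#'
#' `section_to_table()` returns one row per fiber with the canonical columns
#' `fiber_id, x_um, y_um, axon_diameter_um, fiber_diameter_um`;
#' `table_to_section()` validates such a table (from this package or traced
#' from real micrographs) and rebuilds a `nerve_section`. The round trip is
#' lossless.
#'
#' @param section A `nerve_section`.
#' @return `section_to_table()`: a plain tibble.
#' @export
section_to_table <- function(section) {
  assert_section(section)
  out <- as_tibble(section)
  class(out) <- setdiff(class(out), "nerve_section")
  attr(out, "section_id") <- NULL
  attr(out, "nerve_radius_um") <- NULL
  attr(out, "cross_sectional_area_um2") <- NULL
  attr(out, "group") <- NULL
  attr(out, "seed") <- NULL
  out[c("fiber_id", "x_um", "y_um", "axon_diameter_um", "fiber_diameter_um")]
}

#' @rdname section_to_table
#' @param table A data frame with the canonical fiber columns.
#' @param nerve_radius_um Nerve radius (μm); required unless present in `meta`.
#' @param cross_sectional_area_um2 Whole-nerve area; defaults to
#'   `pi * nerve_radius_um^2` for synthetic sections, supply the measured
#'   value for imported tables.
#' @param section_id,group,seed Optional metadata.
#' @param check_overlap Also verify that no two fiber disks overlap
#'   (O(n²); off by default for large imports).
#' @return `table_to_section()`: a validated `nerve_section`.
#' @export
table_to_section <- function(table, nerve_radius_um, section_id = "imported",
                             cross_sectional_area_um2 = NULL,
                             group = NA_character_, seed = NA_integer_,
                             check_overlap = FALSE) {
  req <- c("fiber_id", "x_um", "y_um", "axon_diameter_um", "fiber_diameter_um")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop_parse(paste0("Fiber table is missing column(s): ", paste(missing_cols, collapse = ", "), "."))
  tb <- as_tibble(table)[req]
  for (cn in req) {
    if (!is.numeric(tb[[cn]]))
      stop_parse(paste0("Column `", cn, "` must be numeric."))
    if (anyNA(tb[[cn]]))
      stop_parse(paste0("Column `", cn, "` contains missing values (first at row ",
                        which(is.na(tb[[cn]]))[1], ")."))
  }
  if (anyDuplicated(tb$fiber_id))
    stop_parse(paste0("Duplicate fiber_id at row ", which(duplicated(tb$fiber_id))[1], "."))
  bad <- which(!(tb$axon_diameter_um > 0 & tb$axon_diameter_um < tb$fiber_diameter_um))
  if (length(bad))
    stop_parse(paste0("Row ", bad[1], ": need 0 < axon diameter < fiber diameter ",
                      "(got d = ", tb$axon_diameter_um[bad[1]],
                      ", D = ", tb$fiber_diameter_um[bad[1]], ")."))
  if (!is.numeric(nerve_radius_um) || length(nerve_radius_um) != 1 || nerve_radius_um <= 0)
    stop_parse("`nerve_radius_um` must be a single positive number.")
  out_r <- sqrt(tb$x_um^2 + tb$y_um^2) + tb$fiber_diameter_um / 2
  bad <- which(out_r > nerve_radius_um * (1 + 1e-9))
  if (length(bad))
    stop_parse(paste0("Row ", bad[1], ": fiber disk extends outside the nerve boundary."))
  if (check_overlap && nrow(tb) > 1) {
    dx <- outer(tb$x_um, tb$x_um, "-")
    dy <- outer(tb$y_um, tb$y_um, "-")
    lim <- outer(tb$fiber_diameter_um, tb$fiber_diameter_um, "+") / 2
    dist2 <- dx^2 + dy^2
    diag(dist2) <- Inf
    ov <- which(dist2 < (lim * (1 - 1e-12))^2, arr.ind = TRUE)
    if (nrow(ov))
      stop_parse(paste0("Rows ", ov[1, 1], " and ", ov[1, 2], ": fiber disks overlap."))
  }
  new_nerve_section(tb, section_id = section_id, nerve_radius_um = nerve_radius_um,
                    group = group, seed = seed,
                    cross_sectional_area_um2 = cross_sectional_area_um2)
}

#' Read and write fiber tables as CSV with a JSON metadata sidecar
#'
#' The CSV holds the canonical fiber columns; `<path>.json` holds the
#' section metadata (`section_id`, `nerve_radius_um`,
#' `cross_sectional_area_um2`, `group`, `seed`). `read_fiber_table()`
#' rebuilds the validated `nerve_section`.
#'
#' @param section A `nerve_section`.
#' @param path CSV file path.
#' @return `write_fiber_table()` returns `path` invisibly;
#'   `read_fiber_table()` returns a `nerve_section`.
#' @export
write_fiber_table <- function(section, path) {
  assert_section(section)
  tb <- section_to_table(section)
  # 17 significant digits guarantee the written decimal parses back to the
  # identical double, making write -> read -> write byte-stable
  num <- dplyr::mutate(tb, dplyr::across(dplyr::where(is.double),
                                         ~ sprintf("%.17g", .x)))
  readr::write_csv(num, path)
  meta <- as.list(section_meta(section))
  jsonlite::write_json(meta[c("section_id", "nerve_radius_um",
                              "cross_sectional_area_um2", "group", "seed")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiber_table
#' @export
read_fiber_table <- function(path) {
  if (!file.exists(path))
    stop_parse(paste0("No such file: ", path))
  # base read.csv: strtod parsing is correctly rounded, so the 17-digit
  # decimals written by write_fiber_table() reproduce the exact doubles
  tb <- as_tibble(utils::read.csv(path, colClasses = "numeric"))
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop_parse(paste0("Missing metadata sidecar: ", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  table_to_section(tb,
                   nerve_radius_um = meta$nerve_radius_um,
                   cross_sectional_area_um2 = meta$cross_sectional_area_um2,
                   section_id = meta$section_id %||% "imported",
                   group = meta$group %||% NA_character_,
                   seed = meta$seed %||% NA_integer_)
}
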