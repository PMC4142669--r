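#' Paired two-tailed t-test with significance tiers
#'
#' The statistical layer used for all group contrasts: control vs crush
#' nerves of the same animals, LM vs EM estimates of the same nerves, or
#' time point vs pre-operation values. Delegates to [stats::t.test()]
#' (paired, two-sided) in the regular case and handles the degenerate ones
#' explicitly: if every pairwise difference is zero, `t = 0`, `p = 1`; if
#' the differences are constant but nonzero (zero variance), `p = 0` with
#' `degenerate_variance = TRUE`.
#'
#' Significance tiers follow the conventional cutoffs: `*` for p <= 0.05,
#' `**` for p <= 0.01, `***` for p <= 0.001, otherwise `ns`.
#'
#' @param values_a,values_b Equal-length numeric vectors, one value per
#'   animal/section, matched by position.
#' @param label_a,label_b Labels for the two conditions.
#' @return A `paired_comparison` object; `tidy()` returns it as a one-row
#'   tibble with `n`, means, SDs, `t`, `df`, `p_value` and `tier`.
#' @examples
#' cmp <- paired_t_test(c(6, 7, 8, 9, 10), c(5, 5, 5, 5, 5))
#' cmp
#' tidy(cmp)
#' @export
paired_t_test <- function(values_a, values_b, label_a = "a", label_b = "b") {
  if (!is.numeric(values_a) || !is.numeric(values_b))
    stop_stats("Both value vectors must be numeric.")
  if (length(values_a) != length(values_b))
    stop_stats("Paired vectors must have equal length.")
  n <- length(values_a)
  if (n < 2)
    stop_stats("A paired t-test needs at least 2 pairs.")
  if (anyNA(values_a) || anyNA(values_b))
    stop_stats("Missing values are not allowed.")
  diffs <- values_a - values_b
  degenerate <- FALSE
  if (sd(diffs) == 0) {
    degenerate <- TRUE
    if (all(diffs == 0)) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(diffs)) * Inf; p <- 0
    }
  } else {
    ht <- stats::t.test(values_a, values_b, paired = TRUE, alternative = "two.sided")
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(label_a = label_a, label_b = label_b,
         values_a = values_a, values_b = values_b, n = n,
         mean_a = mean(values_a), mean_b = mean(values_b),
         sd_a = sd(values_a), sd_b = sd(values_b),
         t_statistic = t_stat, degrees_of_freedom = n - 1L,
         p_value = p, significance_tier = significance_tier(p),
         degenerate_variance = degenerate),
    class = "paired_comparison"
  )
}

#' Significance tier for a p value
#'
#' @param p p value(s) in `[0, 1]`.
#' @return `"***"` (p <= 0.001), `"**"` (p <= 0.01), `"*"` (p <= 0.05) or `"ns"`.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01  ~ "**",
    p <= 0.05  ~ "*",
    TRUE       ~ "ns"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t-test: %s vs %s (n = %d pairs)\n", x$label_a, x$label_b, x$n))
  cat(sprintf("  %s: %.4g +/- %.4g   %s: %.4g +/- %.4g\n",
              x$label_a, x$mean_a, x$sd_a, x$label_b, x$mean_b, x$sd_b))
  cat(sprintf("  t = %.4g, df = %d, p = %.4g  [%s]%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$significance_tier,
              if (x$degenerate_variance) "  (zero-variance differences)" else ""))
  invisible(x)
}

#' @export
#' @method tidy paired_comparison
tidy.paired_comparison <- function(x, ...) {
  tibble(
    comparison = paste(x$label_a, "vs", x$label_b),
    n = x$n,
    mean_a = x$mean_a, sd_a = x$sd_a,
    mean_b = x$mean_b, sd_b = x$sd_b,
    t = x$t_statistic, df = x$degrees_of_freedom,
    p_value = x$p_value, tier = x$significance_tier,
    degenerate_variance = x$degenerate_variance
  )
}

#' @export
#' @method glance paired_comparison
glance.paired_comparison <- function(x, ...) tidy(x)

#' Per-group mean +/- SD summary
#'
#' @param values Numeric vector of per-section values.
#' @param groups Group label for each value.
#' @return A tibble `group`, `n`, `mean`, `sd`, `label` (formatted
#'   "mean +/- SD"); single-value groups report `sd = 0` with
#'   `sd_degenerate = TRUE`.
#' @examples
#' summarize_groups(c(2, 4, 3, 3, 3), c("a", "a", "b", "b", "b"))
#' @export
summarize_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop_stats("`values` and `groups` must have equal length.")
  if (length(values) == 0)
    stop_stats("Cannot summarize empty groups.")
  dplyr::summarise(
    dplyr::group_by(tibble(value = values, group = as.character(groups)), .data$group),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
    sd_degenerate = dplyr::n() < 2,
    .groups = "drop"
  ) |>
    dplyr::mutate(label = sprintf("%.4g ± %.4g", .data$mean, .data$sd))
}
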