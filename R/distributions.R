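#' Parametric distribution specifications
#'
#' Small constructors for the distributions the synthetic-section generator
#' draws from. Each returns a classed list carrying the family name and its
#' parameters; [draw_dist()] samples from it and [dist_mean()]/[dist_sd()]
#' give closed-form moments (used by tests to compare Monte-Carlo output
#' against theory).
#'
#' * `dist_lognormal(median, sdlog)` — lognormal parameterised by its median
#'   (μm) and the SD of log values; the natural model for right-skewed fiber
#'   calibre spectra.
#' * `dist_truncnorm(mean, sd, lower, upper)` — normal truncated to
#'   `(lower, upper)`; used for g-ratios, whose support must stay in (0,1).
#' * `dist_degenerate(value)` — a point mass, convenient in tests.
#'
#' @param median,sdlog Median (> 0) and log-scale SD (>= 0) of the lognormal.
#' @param mean,sd Location and scale of the untruncated normal (`sd` >= 0).
#' @param lower,upper Truncation bounds, `lower < upper`.
#' @param value The point-mass location.
#' @return An object of class `stereo_dist`.
#' @examples
#' d <- dist_lognormal(median = 3.5, sdlog = 0.35)
#' draw_dist(d, 5, seed = 1)
#' dist_mean(d)
#' @name stereo_dist
NULL

new_dist <- function(family, ...) {
  structure(list(family = family, ...), class = "stereo_dist")
}

#' @rdname stereo_dist
#' @export
dist_lognormal <- function(median, sdlog) {
  if (!is.numeric(median) || length(median) != 1 || median <= 0)
    stop_distribution("`median` of a lognormal must be a single positive number.")
  if (!is.numeric(sdlog) || length(sdlog) != 1 || sdlog < 0)
    stop_distribution("`sdlog` of a lognormal must be a single non-negative number.")
  new_dist("lognormal", meanlog = log(median), sdlog = sdlog)
}

#' @rdname stereo_dist
#' @export
dist_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.numeric(sd) || length(sd) != 1 || sd < 0)
    stop_distribution("`mean` and `sd` must be single numbers with sd >= 0.")
  if (!(lower < upper))
    stop_distribution("Truncation bounds must satisfy lower < upper.")
  new_dist("truncnorm", mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname stereo_dist
#' @export
dist_degenerate <- function(value) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value))
    stop_distribution("`value` must be a single finite number.")
  new_dist("degenerate", value = value)
}

is_dist <- function(x) inherits(x, "stereo_dist")

assert_dist <- function(x, what) {
  if (!is_dist(x))
    stop_distribution(paste0("`", what, "` must be a distribution built with dist_lognormal(), ",
                             "dist_truncnorm() or dist_degenerate()."))
  x
}

#' Draw random variates from a distribution spec
#'
#' Truncated normals are sampled by inverse-CDF on the truncated probability
#' range, so no rejection loop is needed and every draw respects the bounds.
#'
#' @param dist A `stereo_dist` object.
#' @param n Number of draws.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(dist, n, seed = NULL) {
  assert_dist(dist, "dist")
  if (!is.null(seed)) set.seed(seed)
  switch(dist$family,
    lognormal  = rlnorm(n, dist$meanlog, dist$sdlog),
    degenerate = rep(dist$value, n),
    truncnorm  = {
      plo <- pnorm(dist$lower, dist$mean, dist$sd)
      phi <- pnorm(dist$upper, dist$mean, dist$sd)
      qnorm(plo + runif(n) * (phi - plo), dist$mean, dist$sd)
    },
    stop_distribution(paste0("Unknown distribution family '", dist$family, "'."))
  )
}

#' @rdname draw_dist
#' @export
dist_mean <- function(dist) {
  assert_dist(dist, "dist")
  switch(dist$family,
    lognormal  = exp(dist$meanlog + dist$sdlog^2 / 2),
    degenerate = dist$value,
    truncnorm  = {
      a <- (dist$lower - dist$mean) / dist$sd
      b <- (dist$upper - dist$mean) / dist$sd
      z <- pnorm(b) - pnorm(a)
      dist$mean + dist$sd * (dnorm(a) - dnorm(b)) / z
    }
  )
}

#' @rdname draw_dist
#' @export
dist_sd <- function(dist) {
  assert_dist(dist, "dist")
  switch(dist$family,
    lognormal  = sqrt((exp(dist$sdlog^2) - 1)) * exp(dist$meanlog + dist$sdlog^2 / 2),
    degenerate = 0,
    truncnorm  = {
      a <- (dist$lower - dist$mean) / dist$sd
      b <- (dist$upper - dist$mean) / dist$sd
      z <- pnorm(b) - pnorm(a)
      da <- dnorm(a); db <- dnorm(b)
      t1 <- if (is.finite(a)) a * da else 0
      t2 <- if (is.finite(b)) b * db else 0
      dist$sd * sqrt(1 + (t1 - t2) / z - ((da - db) / z)^2)
    }
  )
}

#' @export
print.stereo_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<stereo_dist ", x$family, "> ",
      paste(names(pars), signif(unlist(pars), 4), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
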