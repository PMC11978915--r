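# Per-ward service-time distributions.
#
# Each ward gets a distribution fitted to its observed lengths of stay;
# draws are bounded to [min(LOS), max(LOS)] by rejection sampling, so the
# service time handed to the flow engine always lies within the observed
# range for that ward.

.FAMILIES <- c("lognormal", "truncated-normal", "uniform", "constant")

#' Construct a service-time distribution
#'
#' Usually created via [fit_distribution()]. Draws from the distribution are
#' guaranteed to lie in `[lower, upper]` hours.
#'
#' @param family one of `"lognormal"`, `"truncated-normal"`, `"uniform"`,
#'   `"constant"`
#' @param params named list of family parameters: `meanlog`/`sdlog`
#'   (lognormal), `mean`/`sd` (truncated-normal), none (uniform), `value`
#'   (constant)
#' @param lower,upper bounds in hours, `0 < lower <= upper`
#' @param note optional fitting note (e.g. a constant fallback)
#' @return an object of class `service_dist`
#' @export
service_distribution <- function(family, params = list(), lower, upper,
                                 note = NULL) {
  family <- match.arg(family, .FAMILIES)
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || lower > upper)
    stop("bounds must satisfy 0 < lower <= upper")
  if (family == "constant") {
    if (is.null(params$value)) params$value <- lower
    if (abs(lower - upper) > 0 || abs(params$value - lower) > 0)
      stop("constant family requires lower = upper = value")
  }
  structure(list(family = family, params = params,
                 lower = lower, upper = upper, note = note),
            class = "service_dist")
}

#' @export
print.service_dist <- function(x, ...) {
  pv <- if (length(x$params))
    paste(names(x$params), signif(unlist(x$params), 6),
          sep = "=", collapse = ", ") else ""
  cat(sprintf("<service_dist> %s [%g, %g] h %s\n", x$family,
              x$lower, x$upper, pv))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Fit a service-time distribution to observed lengths of stay
#'
#' Bounds are always the min and max of the observations. Parameters:
#' lognormal uses the mean and standard deviation of the log values;
#' truncated-normal uses the raw mean and standard deviation; uniform needs
#' only the bounds; constant requires a single distinct value. When a family
#' needs a spread but the observations hold a single distinct value, the fit
#' falls back to a constant distribution (recorded in `$note`, not an
#' error).
#'
#' @param los_values numeric vector of lengths of stay in hours, all > 0
#' @param family distribution family (default `"lognormal"`: hospital
#'   lengths of stay are right-skewed)
#' @return a [service_distribution()]
#' @examples
#' fit_distribution(c(2, 4, 8), "lognormal")
#' @export
fit_distribution <- function(los_values, family = "lognormal") {
  family <- match.arg(family, .FAMILIES)
  los_values <- as.numeric(los_values)
  if (length(los_values) == 0) stop("los_values must be non-empty")
  if (any(!is.finite(los_values) | los_values <= 0))
    stop("all length-of-stay values must be finite and > 0")
  lo <- min(los_values); hi <- max(los_values)

  single <- length(unique(los_values)) == 1L
  if (family == "constant" || (single && family != "uniform")) {
    note <- if (family != "constant")
      sprintf("single distinct value; %s fit fell back to constant", family)
    if (single)
      return(service_distribution("constant", list(value = lo), lo, lo,
                                  note = note))
    stop("constant family requires a single distinct value")
  }

  switch(family,
    lognormal = service_distribution(
      "lognormal",
      list(meanlog = mean(log(los_values)), sdlog = stats::sd(log(los_values))),
      lo, hi),
    `truncated-normal` = service_distribution(
      "truncated-normal",
      list(mean = mean(los_values), sd = stats::sd(los_values)),
      lo, hi),
    uniform = service_distribution("uniform", list(), lo, hi))
}

.draw_raw <- function(dist, n) {
  switch(dist$family,
    lognormal = stats::rlnorm(n, dist$params$meanlog, dist$params$sdlog),
    `truncated-normal` = stats::rnorm(n, dist$params$mean, dist$params$sd),
    uniform = stats::runif(n, dist$lower, dist$upper),
    constant = rep(dist$params$value, n))
}

#' Draw bounded service times
#'
#' Rejection sampling: each draw is redrawn until it falls inside
#' `[lower, upper]`, up to `max_attempts` rounds; any still out of range are
#' clamped to the nearest bound, which guarantees termination even for
#' degenerate bounds. Uses R's global random stream, so reproducibility
#' follows from `set.seed()`.
#'
#' @param dist a `service_dist`
#' @param n number of draws
#' @param max_attempts rejection rounds before clamping (default 1000)
#' @return numeric vector of `n` service times in hours, all within bounds
#' @export
sample_service_time <- function(dist, n = 1L, max_attempts = 1000L) {
  stopifnot(inherits(dist, "service_dist"), n >= 1)
  x <- .draw_raw(dist, n)
  if (dist$family %in% c("uniform", "constant")) return(x)
  bad <- which(x < dist$lower | x > dist$upper)
  attempts <- 1L
  while (length(bad) && attempts < max_attempts) {
    x[bad] <- .draw_raw(dist, length(bad))
    bad <- which(x < dist$lower | x > dist$upper)
    attempts <- attempts + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], dist$lower), dist$upper)
  x
}
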