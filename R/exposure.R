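#' Exposure distributions fitted by the method of moments
#'
#' In the comparative risk assessment framework the exposure of a population
#' stratum to a continuous risk factor (body-mass index, fasting plasma
#' glucose, fruit intake, ...) is summarised as a mean and a standard
#' deviation, and a parametric distribution `P(x)` is recovered from those two
#' moments. `fit_mom()` performs that moment matching for the supported
#' families and attaches the integration support `[l, m]` used by the PAF
#' integral.
#'
#' Moment matching is done on the untruncated family; the density is then
#' renormalized over the support so that it integrates to one. This is the
#' usual "simple MoM" approximation: with the default support of six standard
#' deviations around the mean (clipped to the family's natural range) the
#' clipped mass is negligible for the families supported here.
#'
#' @param mean Stratum mean exposure, in the risk's exposure units.
#' @param sd Stratum standard deviation of exposure; `sd = 0` yields a point
#'   mass at `mean` whatever the requested family.
#' @param family One of `"normal"`, `"lognormal"`, `"gamma"`, `"point_mass"`.
#'   Categorical exposures are built with [categorical_exposure()] instead.
#' @param support Numeric length-2 vector `c(l, m)`, the minimum and maximum
#'   exposure levels over which the PAF integral runs. Defaults to
#'   `mean ± 6 sd`, clipped below at 0 for the non-negative families
#'   (lognormal, gamma).
#' @param risk,stratum Optional identifiers carried along for reporting.
#'
#' @return An object of class `exposure_dist`.
#' @examples
#' d <- fit_mom(27, 4, "normal")
#' exposure_density(d, 27)
#' exposure_quantile(d, 0.85)
#' @export
fit_mom <- function(mean, sd, family = c("normal", "lognormal", "gamma", "point_mass"),
                    support = NULL, risk = NULL, stratum = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    abort_craburden("`mean` must be a single finite number.", "fit")
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    abort_craburden("`sd` must be a single non-negative number.", "fit")
  }
  if (sd == 0) family <- "point_mass"

  if (family %in% c("lognormal", "gamma") && mean <= 0) {
    abort_craburden(
      sprintf("Family '%s' needs a positive mean; got %g.", family, mean),
      "fit"
    )
  }

  lower_bound <- if (family %in% c("lognormal", "gamma")) 0 else -Inf
  if (is.null(support)) {
    support <- c(max(lower_bound, mean - 6 * sd), mean + 6 * sd)
    if (family == "point_mass") support <- c(mean, mean)
  }
  if (length(support) != 2L || !is.numeric(support) || any(is.na(support))) {
    abort_craburden("`support` must be a numeric length-2 vector c(l, m).", "fit")
  }
  if (family != "point_mass" && support[1] >= support[2]) {
    abort_craburden("`support` must satisfy l < m.", "fit")
  }
  if (mean < support[1] || mean > support[2]) {
    abort_craburden(
      sprintf("`mean` (%g) lies outside the support [%g, %g].",
              mean, support[1], support[2]),
      "fit"
    )
  }

  par <- switch(family,
    normal = list(mu = mean, sigma = sd),
    lognormal = {
      sigma2 <- log(1 + (sd / mean)^2)
      list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    gamma = list(shape = (mean / sd)^2, scale = sd^2 / mean),
    point_mass = list(at = mean)
  )

  structure(
    list(
      family = family, mean = mean, sd = sd, support = support,
      par = par, risk = risk, stratum = stratum,
      categories = NULL, prevalences = NULL, values = NULL
    ),
    class = "exposure_dist"
  )
}

#' Categorical exposure distribution
#'
#' Represents exposure split into discrete categories with prevalences summing
#' to one. Optional numeric `values` place each category on the exposure axis,
#' which lets a categorical distribution act as a mixture of point masses in
#' the continuous PAF integral.
#'
#' @param categories Character vector of category labels.
#' @param prevalences Numeric prevalences, summing to 1 within `1e-9`.
#' @param values Optional numeric exposure value per category.
#' @inheritParams fit_mom
#' @return An object of class `exposure_dist` with `family = "categorical"`.
#' @export
categorical_exposure <- function(categories, prevalences, values = NULL,
                                 risk = NULL, stratum = NULL) {
  if (length(categories) != length(prevalences) || length(categories) < 1L) {
    abort_craburden("`categories` and `prevalences` must have equal positive length.", "fit")
  }
  if (any(prevalences < 0) || abs(sum(prevalences) - 1) > 1e-9) {
    abort_craburden("`prevalences` must be non-negative and sum to 1 within 1e-9.", "fit")
  }
  if (!is.null(values) && length(values) != length(categories)) {
    abort_craburden("`values` must match `categories` in length.", "fit")
  }
  support <- if (is.null(values)) c(NA_real_, NA_real_) else range(values)
  mean <- if (is.null(values)) NA_real_ else sum(prevalences * values)
  sd <- if (is.null(values)) NA_real_ else sqrt(max(0, sum(prevalences * values^2) - mean^2))
  structure(
    list(
      family = "categorical", mean = mean, sd = sd, support = support,
      par = NULL, risk = risk, stratum = stratum,
      categories = as.character(categories), prevalences = prevalences,
      values = values
    ),
    class = "exposure_dist"
  )
}

#' @export
print.exposure_dist <- function(x, ...) {
  cat(sprintf(
    "<exposure_dist> family=%s mean=%.4g sd=%.4g support=[%.4g, %.4g]\n",
    x$family, x$mean, x$sd, x$support[1], x$support[2]
  ))
  invisible(x)
}

# untruncated cdf of the underlying family
.family_cdf <- function(dist, x) {
  switch(dist$family,
    normal = stats::pnorm(x, dist$par$mu, dist$par$sigma),
    lognormal = stats::plnorm(x, dist$par$meanlog, dist$par$sdlog),
    gamma = stats::pgamma(x, shape = dist$par$shape, scale = dist$par$scale),
    abort_craburden(sprintf("No continuous CDF for family '%s'.", dist$family), "domain")
  )
}

.family_pdf <- function(dist, x) {
  switch(dist$family,
    normal = stats::dnorm(x, dist$par$mu, dist$par$sigma),
    lognormal = stats::dlnorm(x, dist$par$meanlog, dist$par$sdlog),
    gamma = stats::dgamma(x, shape = dist$par$shape, scale = dist$par$scale),
    abort_craburden(sprintf("No continuous density for family '%s'.", dist$family), "domain")
  )
}

.family_quantile <- function(dist, p) {
  switch(dist$family,
    normal = stats::qnorm(p, dist$par$mu, dist$par$sigma),
    lognormal = stats::qlnorm(p, dist$par$meanlog, dist$par$sdlog),
    gamma = stats::qgamma(p, shape = dist$par$shape, scale = dist$par$scale),
    abort_craburden(sprintf("No quantile function for family '%s'.", dist$family), "domain")
  )
}

# mass of the untruncated family inside the support; used for renormalization
.support_mass <- function(dist) {
  .family_cdf(dist, dist$support[2]) - .family_cdf(dist, dist$support[1])
}

#' Exposure density P(x)
#'
#' Density of the fitted exposure distribution, renormalized over its support
#' so that it integrates to one. Evaluating outside the support is a domain
#' error.
#'
#' @param dist An [fit_mom()] `exposure_dist`.
#' @param x Exposure values within the support.
#' @return Numeric density values.
#' @export
exposure_density <- function(dist, x) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (dist$family == "categorical") {
    abort_craburden("Categorical exposures have no continuous density; use prevalences.", "domain")
  }
  if (any(x < dist$support[1] | x > dist$support[2])) {
    abort_craburden(
      sprintf("x outside the exposure support [%g, %g].",
              dist$support[1], dist$support[2]),
      "domain"
    )
  }
  if (dist$family == "point_mass") {
    # degenerate: density is a Dirac atom; return Inf at the atom, 0 elsewhere
    return(ifelse(x == dist$par$at, Inf, 0))
  }
  .family_pdf(dist, x) / .support_mass(dist)
}

#' Exposure quantile function
#'
#' Inverse CDF of the (support-truncated) exposure distribution. Used, among
#' other things, to place the TMREL of protective risks at the 85th exposure
#' percentile.
#'
#' @inheritParams exposure_density
#' @param q Probabilities strictly between 0 and 1.
#' @return Exposure values within the support, monotone in `q`.
#' @export
exposure_quantile <- function(dist, q) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (any(q <= 0 | q >= 1)) {
    abort_craburden("Quantile probabilities must lie strictly in (0, 1).", "domain")
  }
  if (dist$family == "point_mass") {
    return(rep(dist$par$at, length(q)))
  }
  if (dist$family == "categorical") {
    if (is.null(dist$values)) {
      abort_craburden("Categorical exposure without numeric `values` has no quantiles.", "domain")
    }
    ord <- order(dist$values)
    cum <- cumsum(dist$prevalences[ord])
    return(vapply(q, function(p) dist$values[ord][which(cum >= p - 1e-12)[1]], numeric(1)))
  }
  lo <- .family_cdf(dist, dist$support[1])
  hi <- .family_cdf(dist, dist$support[2])
  .family_quantile(dist, lo + q * (hi - lo))
}

#' Sample exposures
#'
#' Draws from the support-truncated exposure distribution by inverse-CDF
#' transform. Uses the current RNG state; seed management is the caller's
#' responsibility.
#'
#' @inheritParams exposure_density
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
exposure_sample <- function(dist, n) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (dist$family == "point_mass") {
    return(rep(dist$par$at, n))
  }
  if (dist$family == "categorical") {
    if (is.null(dist$values)) {
      abort_craburden("Categorical exposure without numeric `values` cannot be sampled.", "domain")
    }
    return(sample(dist$values, n, replace = TRUE, prob = dist$prevalences))
  }
  u <- stats::runif(n)
  lo <- .family_cdf(dist, dist$support[1])
  hi <- .family_cdf(dist, dist$support[2])
  .family_quantile(dist, lo + u * (hi - lo))
}
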