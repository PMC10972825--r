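#' Population attributable fraction for a continuous exposure
#'
#' Computes
#' \deqn{PAF = \frac{\int_l^m RR(x) P(x) dx - RR(TMREL)}{\int_l^m RR(x) P(x) dx}}
#' where `P(x)` is the stratum's exposure density over its support `[l, m]`
#' and `RR(TMREL)` is the relative risk at the counterfactual exposure level.
#'
#' The integral is evaluated with adaptive quadrature (absolute tolerance
#' `1e-8`); if the adaptive rule fails to converge a fixed 2001-point Simpson
#' rule over the support is used instead. Point-mass and categorical
#' distributions are handled analytically, not numerically: a point mass at
#' `x*` gives `(RR(x*) - RR(TMREL)) / RR(x*)`, and a categorical distribution
#' with numeric category values reduces to the discrete sum, so a mixture of
#' point masses agrees with [paf_discrete()] exactly.
#'
#' Negative PAFs are returned as computed (a population on average below the
#' counterfactual risk has negative attributable burden); clip at the
#' reporting layer if needed.
#'
#' @param dist An [fit_mom()] or [categorical_exposure()] distribution.
#' @param curve An [rr_curve()] sharing the risk's exposure units.
#' @param tmrel The resolved TMREL exposure value (see [resolve_tmrel()]).
#' @param abs_tol Absolute tolerance for the adaptive quadrature.
#' @return A single PAF in `(-Inf, 1]`.
#' @export
paf_continuous <- function(dist, curve, tmrel, abs_tol = 1e-8) {
  stopifnot(inherits(dist, "exposure_dist"), inherits(curve, "rr_curve"))
  rr_t <- rr_at(curve, tmrel)

  if (dist$family == "point_mass") {
    rr_x <- rr_at(curve, dist$par$at)
    return((rr_x - rr_t) / rr_x)
  }
  if (dist$family == "categorical") {
    if (is.null(dist$values)) {
      abort_craburden(
        "Categorical exposure needs numeric `values` for the continuous PAF formula.",
        "domain"
      )
    }
    mean_rr <- sum(dist$prevalences * rr_at(curve, dist$values))
    return((mean_rr - rr_t) / mean_rr)
  }

  l <- dist$support[1]
  m <- dist$support[2]
  f <- function(x) rr_at(curve, x) * exposure_density(dist, x)
  mean_rr <- tryCatch(
    {
      q <- stats::integrate(f, l, m, abs.tol = abs_tol, subdivisions = 500L)
      if (q$message != "OK") stop(q$message)
      q$value
    },
    error = function(e) .simpson(f, l, m, n = 2001L)
  )
  if (!is.finite(mean_rr) || mean_rr <= 0) {
    abort_craburden(
      sprintf("Quadrature of RR(x)P(x) did not yield a positive finite value (got %g).", mean_rr),
      "numeric"
    )
  }
  (mean_rr - rr_t) / mean_rr
}

# composite Simpson rule on n (odd) equally spaced points
.simpson <- function(f, l, m, n = 2001L) {
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(l, m, length.out = n)
  w <- .simpson_weights(n, (m - l) / (n - 1L))
  sum(w * f(x))
}

.simpson_weights <- function(n, h) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

#' Population attributable fraction for a categorical exposure
#'
#' Discrete analogue of [paf_continuous()]:
#' \deqn{PAF = \frac{\sum_x RR(x) P(x) - RR(TMREL)}{\sum_x RR(x) P(x)}}
#' with `P(x)` the category prevalences.
#'
#' @param prevalences Prevalence per category, summing to 1 within `1e-9`.
#' @param rrs Positive RR per category.
#' @param tmrel_category Index or name of the counterfactual category.
#' @return A single PAF.
#' @examples
#' paf_discrete(c(0.5, 0.5), c(1, 2), 1) # 1/3
#' @export
paf_discrete <- function(prevalences, rrs, tmrel_category) {
  if (length(prevalences) != length(rrs)) {
    abort_craburden("`prevalences` and `rrs` must have equal length.", "validation")
  }
  if (any(prevalences < 0) || abs(sum(prevalences) - 1) > 1e-9) {
    abort_craburden("`prevalences` must be non-negative and sum to 1 within 1e-9.", "validation")
  }
  if (any(rrs <= 0)) {
    abort_craburden("`rrs` must be strictly positive.", "validation")
  }
  if (is.character(tmrel_category)) {
    tmrel_category <- match(tmrel_category, names(rrs))
  }
  if (is.na(tmrel_category) || tmrel_category < 1 || tmrel_category > length(rrs)) {
    abort_craburden("`tmrel_category` not found among the categories.", "validation")
  }
  mean_rr <- sum(prevalences * rrs)
  (mean_rr - rrs[[tmrel_category]]) / mean_rr
}

#' Multiplicative combination of PAFs
#'
#' Under the assumption that risk factors act independently, per-risk PAFs
#' combine as `PAF = 1 - prod(1 - PAF_i)`. The result is order-invariant,
#' equals the single input for one risk, and for PAFs in `[0, 1]` never falls
#' below the largest individual PAF nor exceeds 1. Note that draw-level
#' combination with mediation adjustments (as used in published GBD combined
#' estimates) is a different, data-dependent operation; this is the plain
#' independence formula.
#'
#' @param pafs Numeric vector of PAFs, each `<= 1`.
#' @return The combined PAF.
#' @export
combine_pafs <- function(pafs) {
  if (length(pafs) < 1L || any(!is.finite(pafs))) {
    abort_craburden("`pafs` must be a non-empty finite numeric vector.", "validation")
  }
  if (any(pafs > 1)) {
    abort_craburden("Individual PAFs cannot exceed 1.", "validation")
  }
  1 - prod(1 - pafs)
}

#' 95% uncertainty interval from draws
#'
#' Lower and upper bounds are the 2.5th and 97.5th percentiles of the draws
#' under the linear-interpolation percentile rule at ranks `1 + (n - 1) q`
#' (interpolating between adjacent order statistics); the point estimate is
#' the mean of the draws.
#'
#' @param draws Numeric vector of at least 2 draw values.
#' @return Named numeric vector `c(lower, upper, point)`.
#' @export
ui_from_draws <- function(draws) {
  if (length(draws) < 2L || any(!is.finite(draws))) {
    abort_craburden("Need at least 2 finite draws for an uncertainty interval.", "draws")
  }
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = qs[1], upper = qs[2], point = mean(draws))
}

#' Attributable burden from PAFs and total burden
#'
#' Multiplies each stratum's PAF by the total burden for the matching
#' (cause, stratum) cell: attributable DALYs are `PAF x total DALYs`. When
#' draw columns (`draw_1 ... draw_n`) are present in both tables the product
#' is taken draw-wise and the point estimate is the mean of the attributable
#' draws; the identity `attributable + (1 - PAF) x total = total` then holds
#' exactly, draw by draw.
#'
#' @param paf Tibble of PAF estimates with a `cause` column, stratum columns
#'   (any of `location`, `year`, `sex`, `age_group` that are present in both
#'   tables), a `val` column on the proportion scale, and optionally draw
#'   columns.
#' @param burden Tibble of total burden with the same key columns, `val`, and
#'   optionally draw columns.
#' @return A tibble shaped like `burden` with attributable values (plus
#'   `risk`, and `lower`/`upper` when draws are present).
#' @export
attributable_burden <- function(paf, burden) {
  keys <- intersect(
    c("cause", "location", "year", "sex", "age_group"),
    intersect(names(paf), names(burden))
  )
  if (!"cause" %in% keys) {
    abort_craburden("Both tables must carry a `cause` column.", "join")
  }
  pd <- draw_cols(paf)
  bd <- draw_cols(burden)
  use_draws <- length(pd) > 0 && length(bd) > 0
  if (use_draws && !identical(pd, bd)) {
    abort_craburden("PAF and burden tables carry different draw columns.", "join")
  }

  paf_slim <- paf[c(keys, intersect("risk", names(paf)), "val", pd)]
  names(paf_slim)[names(paf_slim) == "val"] <- ".paf_val"
  if (length(pd)) names(paf_slim)[match(pd, names(paf_slim))] <- paste0(".paf_", pd)

  joined <- dplyr::inner_join(paf_slim, burden, by = keys)
  missing <- dplyr::anti_join(paf_slim, burden, by = keys)
  if (nrow(missing) > 0) {
    labs <- apply(missing[keys], 1, paste, collapse = "/")
    abort_craburden(
      sprintf("No burden cell for %d PAF stratum(s): %s",
              nrow(missing), paste(utils::head(labs, 5), collapse = "; ")),
      "join"
    )
  }

  if (use_draws) {
    att <- as.matrix(joined[paste0(".paf_", pd)]) * as.matrix(joined[bd])
    joined[bd] <- att
    joined$val <- rowMeans(att)
    qs <- t(apply(att, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE, type = 7))
    joined$lower <- qs[, 1]
    joined$upper <- qs[, 2]
  } else {
    joined$val <- joined$.paf_val * joined$val
  }
  joined[c(".paf_val", paste0(".paf_", pd))] <- NULL
  as_tibble(joined)
}

# Vectorized draw-level continuous PAF on a fixed Simpson grid.
#
# The pipeline perturbs a stratum's exposure mean across draws while the SD
# and the integration support stay those of the stratum point estimate, so
# the integrand changes only through the density parameters. Evaluating all
# draws on one fixed grid turns the quadrature into a matrix product; with
# >= 1001 Simpson points the error is far below the draw-level noise.
.paf_continuous_draws <- function(means, sd, family, support, curve, tmrel,
                                  n_grid = 1001L) {
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  k <- length(means)
  rr_t <- rr_at(curve, tmrel)
  if (sd == 0) {
    rr_x <- rr_at(curve, means)
    return((rr_x - rr_t) / rr_x)
  }
  x <- seq(support[1], support[2], length.out = n_grid)
  w <- .simpson_weights(n_grid, (support[2] - support[1]) / (n_grid - 1L))
  R <- rr_at(curve, x)
  X <- matrix(x, n_grid, k)
  D <- switch(family,
    normal = stats::dnorm(X, matrix(means, n_grid, k, byrow = TRUE), sd),
    lognormal = {
      s2 <- log(1 + (sd / means)^2)
      ml <- matrix(log(means) - s2 / 2, n_grid, k, byrow = TRUE)
      sl <- matrix(sqrt(s2), n_grid, k, byrow = TRUE)
      stats::dlnorm(X, ml, sl)
    },
    gamma = {
      sh <- matrix((means / sd)^2, n_grid, k, byrow = TRUE)
      sc <- matrix(sd^2 / means, n_grid, k, byrow = TRUE)
      stats::dgamma(X, shape = sh, scale = sc)
    },
    abort_craburden(sprintf("Unsupported draw family '%s'.", family), "numeric")
  )
  denom <- colSums(w * D)
  mean_rr <- colSums((w * R) * D) / denom
  (mean_rr - rr_t) / mean_rr
}
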