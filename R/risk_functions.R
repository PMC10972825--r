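#' Relative-risk curves
#'
#' A relative-risk curve `RR(x)` describes, for one risk-outcome pair, the
#' risk of the outcome at exposure level `x` relative to a reference exposure
#' where `RR = 1`. Three functional forms are supported:
#'
#' * `log_linear` — `RR(x) = exp(beta * (x - reference))`, the standard
#'   assumption when pooled-study effect sizes are converted to a per-unit
#'   log-RR (e.g. high-BMI-like and high-FPG-like risks);
#' * `tabulated_monotone` — a knot table of exposures and RRs, interpolated
#'   monotonically in log-RR with a Fritsch-Carlson monotone cubic Hermite
#'   spline and held constant beyond the outermost knots (dose-response
#'   curves accepted as fitted inputs);
#' * `categorical` — one RR per exposure category.
#'
#' The declared `shape` (monotone_increasing, monotone_decreasing, or
#' inverted_V, i.e. a curve with an interior nadir) is verified against the
#' supplied curve at construction and drives TMREL resolution.
#'
#' @param risk,cause Identifiers of the risk factor and the outcome.
#' @param form Functional form, see Details.
#' @param shape Declared shape of the curve.
#' @param beta Log-RR per unit exposure (`log_linear` only).
#' @param reference Exposure value where `RR = 1`. Defaults to 0 for
#'   `log_linear`; required consistency (`RR(reference) = 1` within `1e-9`)
#'   is checked for tabulated curves.
#' @param knots,values Exposure knots and the RR at each knot
#'   (`tabulated_monotone` only). RRs must be positive.
#' @param category_rrs Named vector of RRs per category (`categorical` only).
#' @return An object of class `rr_curve`.
#' @examples
#' meat <- rr_curve("processed_meat", "colorectal_cancer",
#'   form = "log_linear", beta = log(1.17) / 50,
#'   shape = "monotone_increasing"
#' )
#' rr_at(meat, 50) # 1.17
#' @export
rr_curve <- function(risk, cause,
                     form = c("log_linear", "tabulated_monotone", "categorical"),
                     shape = c("monotone_increasing", "monotone_decreasing", "inverted_V"),
                     beta = NULL, reference = NULL,
                     knots = NULL, values = NULL, category_rrs = NULL) {
  form <- match.arg(form)
  shape <- match.arg(shape)

  if (form == "log_linear") {
    if (is.null(beta) || !is.finite(beta)) {
      abort_craburden("log_linear curves need a finite `beta`.", "curve")
    }
    if (is.null(reference)) reference <- 0
    implied <- if (beta > 0) "monotone_increasing" else if (beta < 0) "monotone_decreasing" else NA
    if (is.na(implied) || implied != shape) {
      abort_craburden(
        sprintf("Declared shape '%s' contradicts beta = %g for a log-linear curve.", shape, beta),
        "shape"
      )
    }
  } else if (form == "tabulated_monotone") {
    if (is.null(knots) || is.null(values) || length(knots) != length(values) || length(knots) < 2L) {
      abort_craburden("Tabulated curves need matching `knots` and `values` (>= 2).", "curve")
    }
    if (is.unsorted(knots, strictly = TRUE)) {
      abort_craburden("`knots` must be strictly increasing.", "curve")
    }
    if (any(values <= 0)) {
      abort_craburden("RR values must be strictly positive.", "curve")
    }
    .check_shape(values, shape)
    if (is.null(reference)) {
      hit <- which(abs(values - 1) <= 1e-9)
      if (length(hit) == 0) {
        abort_craburden("No knot has RR = 1; supply `reference` explicitly.", "curve")
      }
      reference <- knots[hit[1]]
    }
  } else {
    if (is.null(category_rrs) || length(category_rrs) < 1L || any(category_rrs <= 0)) {
      abort_craburden("Categorical curves need positive `category_rrs`.", "curve")
    }
    if (is.null(reference)) reference <- names(category_rrs)[which.min(category_rrs)]
  }

  curve <- structure(
    list(
      risk = risk, cause = cause, form = form, shape = shape,
      beta = beta, reference = reference,
      knots = knots, values = values, category_rrs = category_rrs,
      interp = NULL
    ),
    class = "rr_curve"
  )
  if (form == "tabulated_monotone") {
    # shape-preserving interpolation in log-RR: monoH.FC per monotone
    # segment; inverted-V curves are split at the nadir knot so the
    # interpolant never undershoots the tabulated minimum
    if (shape == "inverted_V") {
      k <- which.min(values)
      f_left <- stats::splinefun(knots[1:k], log(values[1:k]), method = "monoH.FC")
      f_right <- stats::splinefun(knots[k:length(knots)], log(values[k:length(values)]),
                                  method = "monoH.FC")
      knot_k <- knots[k]
      curve$interp <- function(x) ifelse(x <= knot_k, f_left(x), f_right(x))
    } else {
      curve$interp <- stats::splinefun(knots, log(values), method = "monoH.FC")
    }
    if (abs(rr_at(curve, reference) - 1) > 1e-9) {
      abort_craburden("RR(reference) must equal 1 within 1e-9.", "curve")
    }
  }
  curve
}

.check_shape <- function(values, shape) {
  d <- diff(values)
  ok <- switch(shape,
    monotone_increasing = all(d >= 0) && any(d > 0),
    monotone_decreasing = all(d <= 0) && any(d < 0),
    inverted_V = {
      k <- which.min(values)
      k > 1 && k < length(values) &&
        all(d[seq_len(k - 1)] <= 0) && all(d[k:length(d)] >= 0)
    }
  )
  if (!ok) {
    abort_craburden(
      sprintf("Curve values contradict the declared shape '%s'.", shape),
      "shape"
    )
  }
  invisible(TRUE)
}

#' @export
print.rr_curve <- function(x, ...) {
  cat(sprintf("<rr_curve> %s -> %s [%s, %s]\n", x$risk, x$cause, x$form, x$shape))
  invisible(x)
}

#' Evaluate a relative-risk curve
#'
#' `RR(x)` at exposure `x`. Tabulated curves interpolate in log-RR between
#' knots and hold the end values constant beyond the outermost knots, which
#' avoids explosive exponential extrapolation.
#'
#' @param curve An [rr_curve()].
#' @param x Exposure values (numeric), or category labels for categorical
#'   curves.
#' @return Positive RR values.
#' @export
rr_at <- function(curve, x) {
  stopifnot(inherits(curve, "rr_curve"))
  switch(curve$form,
    log_linear = exp(curve$beta * (x - curve$reference)),
    tabulated_monotone = {
      xc <- pmin(pmax(x, curve$knots[1]), curve$knots[length(curve$knots)])
      exp(curve$interp(xc))
    },
    categorical = {
      if (!all(x %in% names(curve$category_rrs))) {
        abort_craburden("Unknown category label(s) for a categorical curve.", "domain")
      }
      unname(curve$category_rrs[x])
    }
  )
}

#' Convert category-level RRs to a per-unit log-RR slope
#'
#' Pooled and meta-analytic studies often report effect sizes by exposure
#' category. Assuming a linear increase of log-RR with exposure, the
#' categories are converted to an RR per unit increase by regressing log(RR)
#' on the category midpoints (ordinary least squares through the data as
#' given). When the input RRs are exactly log-linear in the midpoints the
#' slope reproduces them exactly.
#'
#' @param category_bounds Either a numeric vector of category midpoints, or a
#'   two-column matrix / data frame of interval bounds whose row midpoints are
#'   used.
#' @param category_rrs Positive RR per category.
#' @return `beta`, the log-RR per unit of exposure.
#' @examples
#' # 17% higher risk per 50 g: categories at 25 g and 75 g
#' category_to_per_unit(c(25, 75), c(1.17, 1.17^2)) # log(1.17)/50
#' @export
category_to_per_unit <- function(category_bounds, category_rrs) {
  if (is.matrix(category_bounds) || is.data.frame(category_bounds)) {
    b <- as.matrix(category_bounds)
    if (ncol(b) != 2L) abort_craburden("Interval bounds need two columns.", "conversion")
    if (any(b[, 1] >= b[, 2])) abort_craburden("Interval bounds must be ordered (lower < upper).", "conversion")
    mid <- rowMeans(b)
  } else {
    mid <- as.numeric(category_bounds)
  }
  if (length(mid) < 2L || length(mid) != length(category_rrs)) {
    abort_craburden("Need >= 2 categories with one RR each.", "conversion")
  }
  if (is.unsorted(mid, strictly = TRUE)) {
    abort_craburden("Category midpoints must be strictly increasing.", "conversion")
  }
  if (any(category_rrs <= 0)) {
    abort_craburden("RRs must be strictly positive.", "conversion")
  }
  y <- log(category_rrs)
  unname(stats::coef(stats::lm(y ~ mid))[["mid"]])
}

#' TMREL specification
#'
#' The theoretical minimum-risk exposure level is the counterfactual exposure
#' that minimizes population risk. Three resolution rules are supported, one
#' per curve shape: harmful monotone-increasing risks have TMREL 0
#' (`fixed_zero`); curves with an interior nadir take the exposure at the
#' nadir (`nadir`); protective monotone-decreasing risks take the 85th
#' percentile of the observed exposure distribution (`percentile_85`). An
#' `explicit_value` rule is available for user-supplied levels.
#'
#' @param rule One of `"fixed_zero"`, `"nadir"`, `"percentile_85"`,
#'   `"explicit_value"`.
#' @param value Exposure value (or, for categorical curves, the reference
#'   category label), required for `explicit_value`.
#' @return An object of class `tmrel_spec`.
#' @export
tmrel_spec <- function(rule = c("fixed_zero", "nadir", "percentile_85", "explicit_value"),
                       value = NULL) {
  rule <- match.arg(rule)
  if (rule == "explicit_value" &&
      (is.null(value) || (!is.character(value) && !is.finite(value)))) {
    abort_craburden("`explicit_value` TMREL needs a finite value or a category label.", "tmrel")
  }
  structure(list(rule = rule, value = value), class = "tmrel_spec")
}

#' Resolve a TMREL to an exposure value
#'
#' @param spec A [tmrel_spec()].
#' @param curve The [rr_curve()] of the risk-outcome pair (needed for the
#'   `nadir` rule).
#' @param dist The stratum's [fit_mom()] exposure distribution (needed for the
#'   `percentile_85` rule).
#' @param grid_n Number of grid points for the nadir search (deterministic;
#'   ties broken toward the lowest exposure).
#' @return The TMREL as a single exposure value.
#' @export
resolve_tmrel <- function(spec, curve = NULL, dist = NULL, grid_n = 10001L) {
  stopifnot(inherits(spec, "tmrel_spec"))
  switch(spec$rule,
    fixed_zero = 0,
    explicit_value = spec$value,
    nadir = {
      if (is.null(curve)) abort_craburden("`nadir` rule needs the RR curve.", "tmrel")
      if (curve$shape != "inverted_V") {
        abort_craburden("`nadir` rule applies only to curves with an interior nadir.", "shape")
      }
      grid <- seq(curve$knots[1], curve$knots[length(curve$knots)], length.out = grid_n)
      grid[which.min(rr_at(curve, grid))]
    },
    percentile_85 = {
      if (is.null(dist)) {
        abort_craburden("`percentile_85` rule needs the exposure distribution.", "tmrel")
      }
      exposure_quantile(dist, 0.85)
    }
  )
}

#' Risk-outcome pair
#'
#' Binds one RR curve and one TMREL rule to a (risk factor, outcome)
#' combination — the unit at which PAFs are computed. If the TMREL can be
#' resolved without an exposure distribution and `RR(TMREL)` exceeds the
#' curve's minimum over its evaluable range, a warning is emitted: the PAF
#' formula subtracts RR at TMREL as-is, and such a pair yields PAFs that are
#' not interpretable as maximal avoidable burden.
#'
#' @param risk,cause Identifiers; must match the curve's.
#' @param curve An [rr_curve()].
#' @param tmrel A [tmrel_spec()].
#' @return An object of class `risk_outcome_pair`.
#' @export
risk_outcome_pair <- function(risk, cause, curve, tmrel) {
  stopifnot(inherits(curve, "rr_curve"), inherits(tmrel, "tmrel_spec"))
  if (!identical(curve$risk, risk) || !identical(curve$cause, cause)) {
    abort_craburden("Curve identifiers do not match the pair's (risk, cause).", "registry")
  }
  if (tmrel$rule %in% c("fixed_zero", "explicit_value", "nadir") &&
      curve$form != "categorical") {
    t <- resolve_tmrel(tmrel, curve = curve)
    lo <- switch(curve$form,
      log_linear = min(0, t),
      tabulated_monotone = curve$knots[1]
    )
    hi <- switch(curve$form,
      log_linear = max(t, curve$reference, 0),
      tabulated_monotone = curve$knots[length(curve$knots)]
    )
    grid <- seq(lo, hi, length.out = 2001L)
    if (rr_at(curve, t) > min(rr_at(curve, grid)) + 1e-9) {
      rlang::warn(sprintf(
        "RR at the resolved TMREL (%g) is not the curve minimum for pair %s -> %s.",
        t, risk, cause
      ))
    }
  }
  structure(list(risk = risk, cause = cause, curve = curve, tmrel = tmrel),
            class = "risk_outcome_pair")
}

#' Risk-outcome registry
#'
#' A validated collection of [risk_outcome_pair()]s keyed by `risk|cause`;
#' duplicate pairs are rejected.
#'
#' @param pairs List of [risk_outcome_pair()] objects.
#' @return A named list of class `risk_registry`.
#' @export
risk_registry <- function(pairs) {
  stopifnot(all(vapply(pairs, inherits, logical(1), "risk_outcome_pair")))
  keys <- vapply(pairs, function(p) paste(p$risk, p$cause, sep = "|"), character(1))
  if (anyDuplicated(keys)) {
    abort_craburden(
      sprintf("Duplicate risk-outcome pair(s): %s",
              paste(unique(keys[duplicated(keys)]), collapse = ", ")),
      "registry"
    )
  }
  names(pairs) <- keys
  structure(pairs, class = "risk_registry")
}
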