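#' Specification of one synthetic risk factor
#'
#' Describes how a risk factor behaves in the synthetic world: the shape of
#' its exposure (continuous family or dichotomous categories), the log-linear
#' RR slope (or exposed-category RR) per associated cause, its development
#' gradient (target rank correlation with SDI), and mild age / sex / period
#' structure. The TMREL rule follows from the kind: harmful continuous risks
#' use `fixed_zero`, protective continuous risks use `percentile_85`, and
#' categorical risks use the unexposed category.
#'
#' @param name Risk identifier.
#' @param kind One of `"continuous_harmful"`, `"categorical_harmful"`,
#'   `"continuous_protective"`.
#' @param causes Character vector of outcome causes this risk affects.
#' @param family Exposure family for continuous risks.
#' @param mean_base Baseline exposure mean (continuous), in exposure units.
#' @param sd_ratio Exposure SD as a fraction of the mean (continuous).
#' @param beta Named numeric: log-RR per exposure unit for each cause
#'   (continuous; negative for protective risks).
#' @param prevalence_base Baseline exposed prevalence (categorical).
#' @param rr_exposed Named numeric: RR of the exposed category per cause
#'   (categorical).
#' @param sdi_rho Target rank correlation between the latent exposure level
#'   and SDI across locations (sign sets the direction).
#' @param sdi_effect Scale of the latent development effect on exposure (log
#'   scale for continuous means, logit scale for prevalences). 0 freezes the
#'   exposure at its base value.
#' @param sex_shift Male-minus-female shift on the same scale.
#' @param year_drift Per-period drift on the same scale (applied to years
#'   after the first).
#' @param age_amplitude Amplitude of the unimodal age profile (0 = flat).
#' @return An object of class `risk_spec`.
#' @export
risk_spec <- function(name,
                      kind = c("continuous_harmful", "categorical_harmful",
                               "continuous_protective"),
                      causes,
                      family = "lognormal", mean_base = NULL, sd_ratio = 0.15,
                      beta = NULL, prevalence_base = NULL, rr_exposed = NULL,
                      sdi_rho = 0.8, sdi_effect = 0.1, sex_shift = 0,
                      year_drift = 0.05, age_amplitude = 0.1) {
  kind <- match.arg(kind)
  if (length(causes) < 1L) abort_craburden("A risk needs at least one cause.", "config")
  if (kind == "categorical_harmful") {
    if (is.null(prevalence_base) || prevalence_base < 0 || prevalence_base > 1) {
      abort_craburden(sprintf("Risk '%s': categorical kind needs `prevalence_base` in [0, 1].", name), "config")
    }
    if (is.null(rr_exposed) || !all(causes %in% names(rr_exposed))) {
      abort_craburden(sprintf("Risk '%s': need `rr_exposed` named for every cause.", name), "config")
    }
  } else {
    if (is.null(mean_base) || mean_base < 0) {
      abort_craburden(sprintf("Risk '%s': continuous kind needs a non-negative `mean_base`.", name), "config")
    }
    if (is.null(beta) || !all(causes %in% names(beta))) {
      abort_craburden(sprintf("Risk '%s': need `beta` named for every cause.", name), "config")
    }
    sign_ok <- if (kind == "continuous_harmful") all(beta[causes] > 0) else all(beta[causes] < 0)
    if (!sign_ok) {
      abort_craburden(sprintf("Risk '%s': beta signs contradict the declared kind.", name), "config")
    }
  }
  structure(
    list(
      name = name, kind = kind, causes = causes, family = family,
      mean_base = mean_base, sd_ratio = sd_ratio, beta = beta,
      prevalence_base = prevalence_base, rr_exposed = rr_exposed,
      sdi_rho = sdi_rho, sdi_effect = sdi_effect, sex_shift = sex_shift,
      year_drift = year_drift, age_amplitude = age_amplitude
    ),
    class = "risk_spec"
  )
}

#' Default synthetic risk factors
#'
#' Three archetypes covering the TMREL rules: a high-BMI-like harmful
#' continuous risk (lognormal exposure around 27 units, RR rising ~1.5-2% per
#' unit), a tobacco-like dichotomous risk (30% baseline exposed prevalence,
#' RR 2.5), and a fruit-intake-like protective risk (lognormal around 150
#' units, RR falling ~5% per 50 units, TMREL at the 85th exposure
#' percentile). Exposure levels rise with development (positive SDI rank
#' correlation) as the emulated extract's wealth-related risks do.
#'
#' @return A list of [risk_spec()]s.
#' @export
default_risk_specs <- function() {
  list(
    risk_spec("high_bmi_like",
      kind = "continuous_harmful", causes = c("colorectal_cancer", "liver_cancer"),
      family = "lognormal", mean_base = 27, sd_ratio = 0.15,
      beta = c(colorectal_cancer = log(1.02), liver_cancer = log(1.015)),
      sdi_rho = 0.8, sdi_effect = 0.08, sex_shift = -0.03, year_drift = 0.06,
      age_amplitude = 0.08
    ),
    risk_spec("tobacco_like",
      kind = "categorical_harmful", causes = "lung_cancer",
      prevalence_base = 0.3, rr_exposed = c(lung_cancer = 2.5),
      sdi_rho = 0.8, sdi_effect = 0.8, sex_shift = 0.6, year_drift = -0.2,
      age_amplitude = 0.15
    ),
    risk_spec("fruit_intake_like",
      kind = "continuous_protective", causes = "colorectal_cancer",
      family = "lognormal", mean_base = 150, sd_ratio = 0.25,
      beta = c(colorectal_cancer = -log(1.05) / 50),
      sdi_rho = 0.6, sdi_effect = 0.12, sex_shift = -0.05, year_drift = 0.05,
      age_amplitude = 0.05
    )
  )
}

#' Synthetic-world configuration
#'
#' Parameters of the synthetic GBD-like dataset: its strata (locations,
#' years, 5-year age bands, sexes), risk factors and causes, the number of
#' uncertainty draws, the random seed, and the draw-noise levels. The default
#' world is desk-scale: 10 locations x 2 years x 8 age bands x 2 sexes x
#' 3 risks x 3 causes with 1000 draws.
#'
#' @param n_locations Number of synthetic locations (>= 1).
#' @param years Calendar years (distinct, increasing).
#' @param age_groups Ordered, non-overlapping 5-year bands such as
#'   `"40-44"`; an open-ended final band like `"95+"` is allowed.
#' @param sexes Subset of `c("Male", "Female")`.
#' @param risks List of [risk_spec()]s.
#' @param causes Character vector of cause names; every risk's causes must be
#'   among them.
#' @param draws Number of uncertainty draws (>= 1).
#' @param seed Integer random seed; a fixed seed makes [generate_world()]
#'   byte-identical across runs.
#' @param cv_exposure Coefficient of variation of the multiplicative
#'   draw noise on continuous exposure means.
#' @param sd_logit_prevalence SD of logit-scale draw noise on categorical
#'   prevalences.
#' @param cv_dalys Coefficient of variation of the multiplicative lognormal
#'   draw noise on stratum DALYs (kept multiplicative so draws stay
#'   positive).
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_locations = 10,
                         years = c(1990, 2019),
                         age_groups = c("40-44", "45-49", "50-54", "55-59",
                                        "60-64", "65-69", "70-74", "75-79"),
                         sexes = c("Male", "Female"),
                         risks = default_risk_specs(),
                         causes = c("lung_cancer", "colorectal_cancer", "liver_cancer"),
                         draws = 1000,
                         seed = 17,
                         cv_exposure = 0.02,
                         sd_logit_prevalence = 0.05,
                         cv_dalys = 0.1) {
  if (n_locations < 1) abort_craburden("`n_locations` must be >= 1.", "config")
  if (draws < 1) abort_craburden("`draws` must be >= 1.", "config")
  if (length(years) < 1 || anyDuplicated(years) || is.unsorted(years)) {
    abort_craburden("`years` must be distinct and increasing.", "config")
  }
  if (length(causes) < 1 || length(sexes) < 1 || length(age_groups) < 1) {
    abort_craburden("`age_groups`, `sexes` and `causes` must be non-empty.", "config")
  }
  if (!all(sexes %in% c("Male", "Female"))) {
    abort_craburden("`sexes` must be a subset of c('Male', 'Female').", "config")
  }
  .check_age_bands(age_groups)
  stopifnot(all(vapply(risks, inherits, logical(1), "risk_spec")))
  for (r in risks) {
    unknown <- setdiff(r$causes, causes)
    if (length(unknown) > 0) {
      abort_craburden(
        sprintf("Risk '%s' references unknown cause(s): %s.", r$name,
                paste(unknown, collapse = ", ")),
        "config"
      )
    }
  }
  if (anyDuplicated(vapply(risks, `[[`, character(1), "name"))) {
    abort_craburden("Duplicate risk names.", "config")
  }
  structure(
    list(
      n_locations = as.integer(n_locations), years = as.integer(years),
      age_groups = age_groups, sexes = sexes, risks = risks, causes = causes,
      draws = as.integer(draws), seed = as.integer(seed),
      cv_exposure = cv_exposure, sd_logit_prevalence = sd_logit_prevalence,
      cv_dalys = cv_dalys
    ),
    class = "world_config"
  )
}

.check_age_bands <- function(bands) {
  m <- regmatches(bands, regexec("^(\\d+)(?:-(\\d+)|\\+)$", bands))
  if (any(vapply(m, length, integer(1)) == 0)) {
    abort_craburden("Age bands must look like '40-44' or '95+'.", "config")
  }
  lo <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  hi <- vapply(m, function(x) if (x[3] == "") Inf else as.numeric(x[3]), numeric(1))
  if (any(hi < lo)) abort_craburden("Age band upper bound below lower bound.", "config")
  if (length(bands) > 1) {
    if (any(diff(lo) <= 0) || any(hi[-length(hi)] >= lo[-1])) {
      abort_craburden("Age bands must be ordered and non-overlapping.", "config")
    }
  }
  if (any(is.infinite(hi[-length(hi)]))) {
    abort_craburden("Only the last age band may be open-ended.", "config")
  }
  invisible(TRUE)
}

# unimodal age multiplier on the log/logit scale, peak at ~2/3 of the bands
.age_profile <- function(n_ages, amplitude) {
  i <- seq_len(n_ages)
  peak <- 2 / 3 * n_ages
  amplitude * exp(-((i - peak) / (0.35 * n_ages + 0.5))^2)
}

# generator-side quadrature: plain trapezoid on 4001 points, deliberately a
# different rule and resolution from the engine's adaptive/Simpson path so
# parameter recovery is a genuine cross-check
.truth_paf_continuous <- function(family, mean, sd, beta, protective) {
  if (sd == 0) {
    rr_x <- exp(beta * mean)
    rr_t <- if (protective) rr_x else 1
    return((rr_x - rr_t) / rr_x)
  }
  l <- max(0, mean - 6 * sd)
  m <- mean + 6 * sd
  x <- seq(l, m, length.out = 4001)
  d <- switch(family,
    lognormal = {
      s2 <- log(1 + (sd / mean)^2)
      stats::dlnorm(x, log(mean) - s2 / 2, sqrt(s2))
    },
    normal = stats::dnorm(x, mean, sd),
    gamma = stats::dgamma(x, shape = (mean / sd)^2, scale = sd^2 / mean),
    abort_craburden(sprintf("Unsupported truth family '%s'.", family), "config")
  )
  h <- x[2] - x[1]
  trapz <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  mass <- trapz(d)
  mean_rr <- trapz(exp(beta * x) * d) / mass
  rr_t <- if (protective) {
    # 85th percentile of the support-truncated distribution
    cdf <- switch(family,
      lognormal = function(q) {
        s2 <- log(1 + (sd / mean)^2)
        stats::plnorm(q, log(mean) - s2 / 2, sqrt(s2))
      },
      normal = function(q) stats::pnorm(q, mean, sd),
      gamma = function(q) stats::pgamma(q, shape = (mean / sd)^2, scale = sd^2 / mean)
    )
    p <- cdf(l) + 0.85 * (cdf(m) - cdf(l))
    q85 <- stats::uniroot(function(q) cdf(q) - p, c(l, m), tol = 1e-10)$root
    exp(beta * q85)
  } else {
    1 # RR at TMREL = 0 with reference 0
  }
  (mean_rr - rr_t) / mean_rr
}

#' Generate a synthetic GBD-like world
#'
#' Builds a fully synthetic, self-contained dataset shaped like a GBD results
#' extract: stratified exposure means/SDs and prevalences with draw-level
#' noise, per-cause baseline DALYs with draws, per-stratum populations, an
#' SDI table whose development gradient is rank-correlated with the
#' exposures, a risk-outcome registry, and — crucially — ground-truth PAFs
#' computed on the generator side by its own quadrature/closed forms, so that
#' the analysis pipeline can be checked for parameter recovery. Output is
#' byte-identical for a fixed seed.
#'
#' @param config A [world_config()].
#' @return An object of class `cra_world`: a list with elements `config`,
#'   `exposure`, `burden`, `population`, `sdi`, `registry`, `ground_truth`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(config$seed, .generate_world_impl(config))
}

.generate_world_impl <- function(config) {
  n_loc <- config$n_locations
  locs <- sprintf("location_%02d", seq_len(n_loc))
  years <- config$years
  ages <- config$age_groups
  sexes <- config$sexes
  n_draws <- config$draws
  dnames <- paste0("draw_", seq_len(n_draws))

  # --- SDI: one development latent per location, slow improvement over time
  z_dev <- stats::rnorm(n_loc)
  comp_noise <- matrix(stats::rnorm(3 * n_loc, 0, 0.25), n_loc, 3)
  base_comp <- stats::plogis(0.9 * z_dev + comp_noise) # n_loc x 3 in (0,1)
  sdi <- do.call(rbind, lapply(seq_along(years), function(yi) {
    shift <- 0.15 * (yi - 1) / max(1, length(years) - 1)
    comp <- base_comp + shift * (1 - base_comp)
    tibble(
      location = locs, year = years[yi],
      tfu25 = comp[, 1], edu15 = comp[, 2], ldi = comp[, 3],
      sdi = compute_sdi(comp[, 1], comp[, 2], comp[, 3])
    )
  }))

  strata <- tidyr::expand_grid(
    location = locs, year = years, sex = sexes, age_group = ages
  )
  age_idx <- match(strata$age_group, ages)
  year_idx <- match(strata$year, years)
  sex_sign <- ifelse(strata$sex == "Male", 1, -1)

  # --- population: lognormal location size, declining age structure, growth
  loc_scale <- exp(stats::rnorm(n_loc, 0, 0.3))
  population <- strata
  population$population <- 1e6 * loc_scale[match(population$location, locs)] *
    0.9^(age_idx - 1) * (1 + 0.25 * (year_idx - 1) / max(1, length(years) - 1))

  # --- exposures and ground-truth PAFs
  exposure_rows <- list()
  truth_rows <- list()
  pairs <- list()

  for (spec in config$risks) {
    rho <- spec$sdi_rho
    eps <- stats::rnorm(n_loc)
    latent_loc <- rho * z_dev + sqrt(max(0, 1 - rho^2)) * eps
    latent <- latent_loc[match(strata$location, locs)]
    age_mult <- .age_profile(length(ages), spec$age_amplitude)[age_idx]
    shift <- spec$sdi_effect * latent + spec$sex_shift * sex_sign / 2 +
      spec$year_drift * (year_idx - 1) + age_mult

    if (spec$kind == "categorical_harmful") {
      p <- stats::plogis(stats::qlogis(spec$prevalence_base) + shift)
      noise <- matrix(stats::rnorm(nrow(strata) * n_draws, 0, config$sd_logit_prevalence),
                      nrow(strata), n_draws)
      p_draws <- stats::plogis(stats::qlogis(p) + noise)
      exposed <- strata
      exposed$risk <- spec$name
      exposed$metric <- "prevalence"
      exposed$category <- "exposed"
      exposed$val <- p
      exposed[dnames] <- as.data.frame(p_draws)
      unexposed <- exposed
      unexposed$category <- "unexposed"
      unexposed$val <- 1 - p
      unexposed[dnames] <- as.data.frame(1 - p_draws)
      exposure_rows[[spec$name]] <- dplyr::bind_rows(exposed, unexposed)

      for (cause in spec$causes) {
        r <- spec$rr_exposed[[cause]]
        true_paf <- p * (r - 1) / (1 + p * (r - 1)) # closed form
        tr <- strata
        tr$risk <- spec$name
        tr$cause <- cause
        tr$true_paf <- true_paf
        truth_rows[[paste(spec$name, cause)]] <- tr
        curve <- rr_curve(spec$name, cause,
          form = "categorical", shape = "monotone_increasing",
          category_rrs = c(exposed = r, unexposed = 1)
        )
        pairs[[paste(spec$name, cause)]] <- risk_outcome_pair(
          spec$name, cause, curve, tmrel_spec("explicit_value", value = "unexposed")
        )
      }
    } else {
      protective <- spec$kind == "continuous_protective"
      mean_true <- spec$mean_base * exp(shift)
      sd_true <- spec$sd_ratio * mean_true
      sig <- sqrt(log(1 + config$cv_exposure^2))
      noise <- matrix(exp(stats::rnorm(nrow(strata) * n_draws, -sig^2 / 2, sig)),
                      nrow(strata), n_draws)
      mean_draws <- mean_true * noise

      mrow <- strata
      mrow$risk <- spec$name
      mrow$metric <- "mean"
      mrow$category <- NA_character_
      mrow$val <- mean_true
      mrow[dnames] <- as.data.frame(mean_draws)
      srow <- strata
      srow$risk <- spec$name
      srow$metric <- "sd"
      srow$category <- NA_character_
      srow$val <- sd_true
      srow[dnames] <- as.data.frame(matrix(sd_true, nrow(strata), n_draws))
      exposure_rows[[spec$name]] <- dplyr::bind_rows(mrow, srow)

      for (cause in spec$causes) {
        b <- spec$beta[[cause]]
        tr <- strata
        tr$risk <- spec$name
        tr$cause <- cause
        tr$true_paf <- vapply(
          seq_len(nrow(strata)),
          function(i) .truth_paf_continuous(spec$family, mean_true[i], sd_true[i], b, protective),
          numeric(1)
        )
        truth_rows[[paste(spec$name, cause)]] <- tr
        curve <- rr_curve(spec$name, cause,
          form = "log_linear", beta = b, reference = 0,
          shape = if (protective) "monotone_decreasing" else "monotone_increasing"
        )
        tm <- if (protective) tmrel_spec("percentile_85") else tmrel_spec("fixed_zero")
        pairs[[paste(spec$name, cause)]] <- risk_outcome_pair(spec$name, cause, curve, tm)
      }
    }
  }

  exposure <- as_tibble(dplyr::bind_rows(exposure_rows))
  truth <- as_tibble(dplyr::bind_rows(truth_rows))

  # --- combined ground truth per cause-stratum (independence product)
  combined <- truth |>
    dplyr::group_by(.data$cause, .data$location, .data$year, .data$sex, .data$age_group) |>
    dplyr::summarise(true_paf = 1 - prod(1 - .data$true_paf), .groups = "drop") |>
    dplyr::mutate(risk = "_combined")
  truth <- dplyr::bind_rows(truth, combined)

  # --- baseline DALYs per cause-stratum, with multiplicative lognormal draws
  cause_base <- stats::setNames(
    exp(stats::runif(length(config$causes), log(2e3), log(2e4))),
    config$causes
  )
  burden <- tidyr::expand_grid(cause = config$causes, strata)
  b_age <- match(burden$age_group, ages)
  b_year <- match(burden$year, years)
  burden$measure <- "DALYs"
  burden$metric <- "Number"
  burden$val <- cause_base[burden$cause] *
    loc_scale[match(burden$location, locs)] *
    exp(0.3 * (b_age - 1)) *
    ifelse(burden$sex == "Male", 1.15, 0.9) *
    (1 + 0.5 * (b_year - 1) / max(1, length(years) - 1))
  sig_d <- sqrt(log(1 + config$cv_dalys^2))
  dn <- matrix(exp(stats::rnorm(nrow(burden) * n_draws, -sig_d^2 / 2, sig_d)),
               nrow(burden), n_draws)
  burden[dnames] <- as.data.frame(burden$val * dn)
  burden <- as_tibble(burden[c("measure", "cause", "location", "year", "sex",
                               "age_group", "metric", "val", dnames)])

  # consistency contract: true attributable burden is exactly paf x total
  truth <- dplyr::left_join(
    truth,
    burden[c("cause", "location", "year", "sex", "age_group", "val")],
    by = c("cause", "location", "year", "sex", "age_group")
  )
  truth$true_attributable <- truth$true_paf * truth$val
  truth$val <- NULL

  ground_truth <- structure(
    list(
      true_paf = truth,
      true_exposure_params = exposure[c("risk", "location", "year", "sex",
                                        "age_group", "metric", "category", "val")],
      true_sdi = sdi
    ),
    class = "cra_ground_truth"
  )

  structure(
    list(
      config = config,
      exposure = exposure,
      burden = burden,
      population = as_tibble(population),
      sdi = as_tibble(sdi),
      registry = risk_registry(unname(pairs)),
      ground_truth = ground_truth
    ),
    class = "cra_world"
  )
}

#' @export
print.cra_world <- function(x, ...) {
  cat(sprintf(
    "<cra_world> %d locations x %d years x %d ages x %d sexes; %d risks, %d causes, %d draws (seed %d)\n",
    x$config$n_locations, length(x$config$years), length(x$config$age_groups),
    length(x$config$sexes), length(x$config$risks), length(x$config$causes),
    x$config$draws, x$config$seed
  ))
  invisible(x)
}

#' Look up a generator-side ground-truth PAF
#'
#' Returns the PAF the generator recorded for one (risk, cause, stratum)
#' cell, computed by the generator's own quadrature or closed form —
#' independent of the analysis engine. `risk = "_combined"` addresses the
#' independence-combined PAF across the risks affecting a cause.
#'
#' @param ground_truth The `ground_truth` element of a [generate_world()]
#'   result.
#' @param risk,cause,location,year,sex,age_group Stratum identifiers.
#' @return The true PAF as a single number.
#' @export
ground_truth_paf <- function(ground_truth, risk, cause, location, year, sex, age_group) {
  stopifnot(inherits(ground_truth, "cra_ground_truth"))
  hit <- dplyr::filter(
    ground_truth$true_paf,
    .data$risk == !!risk, .data$cause == !!cause, .data$location == !!location,
    .data$year == !!year, .data$sex == !!sex, .data$age_group == !!age_group
  )
  if (nrow(hit) != 1L) {
    abort_craburden(
      sprintf("Unknown stratum: %s/%s/%s/%s/%s/%s.", risk, cause, location, year, sex, age_group),
      "lookup"
    )
  }
  hit$true_paf
}
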