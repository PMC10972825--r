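#' Standard population weights
#'
#' Direct age-standardization weights: one positive weight per age band,
#' summing to 1 within `1e-12`. Weights may be supplied unnormalized and are
#' rescaled.
#'
#' @param age_groups Character vector of age bands.
#' @param weights Positive weights, one per band.
#' @return A tibble with columns `age_group`, `weight` of class
#'   `standard_population`.
#' @export
standard_population <- function(age_groups, weights) {
  if (length(age_groups) != length(weights) || length(weights) < 1L) {
    abort_craburden("`age_groups` and `weights` must have equal positive length.", "validation")
  }
  if (any(weights <= 0) || any(!is.finite(weights))) {
    abort_craburden("Standard-population weights must be positive and finite.", "validation")
  }
  if (anyDuplicated(age_groups)) {
    abort_craburden("Duplicate age groups in the standard population.", "validation")
  }
  w <- weights / sum(weights)
  structure(
    tibble(age_group = as.character(age_groups), weight = w),
    class = c("standard_population", "tbl_df", "tbl", "data.frame")
  )
}

#' Bundled synthetic standard population
#'
#' A deterministic synthetic standard whose weights decline geometrically
#' across the supplied age bands (each band carrying 82% of the weight of the
#' previous one), loosely mimicking the shape of a world standard population
#' over adult ages. It is a stand-in for analyses that do not supply their
#' own standard; published age-standardized rates use the (unpublished here)
#' GBD standard and are not reproducible with it.
#'
#' @param age_groups Ordered character vector of age bands.
#' @return A [standard_population()].
#' @export
default_standard_population <- function(age_groups) {
  standard_population(age_groups, 0.82^(seq_along(age_groups) - 1))
}

#' Direct age-standardization
#'
#' Weighted sum of age-specific rates with standard-population weights. When
#' the population's own age structure equals the standard weights this equals
#' the crude rate.
#'
#' @param rates Either a named numeric vector (names = age groups) or a tibble
#'   with columns `age_group` and `rate`, in events per 100,000.
#' @param std A [standard_population()] covering every age group.
#' @return The age-standardized rate per 100,000.
#' @export
age_standardize <- function(rates, std) {
  stopifnot(inherits(std, "standard_population"))
  if (is.data.frame(rates)) {
    r <- stats::setNames(rates$rate, rates$age_group)
  } else {
    r <- rates
  }
  missing <- setdiff(std$age_group, names(r))
  if (length(missing) > 0) {
    abort_craburden(
      sprintf("No rate for standard age group(s): %s.", paste(missing, collapse = ", ")),
      "coverage"
    )
  }
  sum(std$weight * r[std$age_group])
}

#' PAF recovered from attributable and total burden
#'
#' `PAF = attributable / total`. With draw vectors the ratio is taken per
#' draw and the point estimate is the mean of the draw-level ratios — which
#' is not, in general, the ratio of the means.
#'
#' @param attributable Attributable burden (scalar or draw vector),
#'   person-years.
#' @param total Total burden on the same strata (scalar or draw vector),
#'   person-years, strictly positive.
#' @return A single PAF (mean of draw-level ratios when vectors are given).
#' @export
paf_from_burden <- function(attributable, total) {
  if (any(total <= 0)) {
    abort_craburden("PAF is undefined for non-positive total burden.", "undefined")
  }
  if (length(total) != length(attributable) && length(total) != 1L) {
    abort_craburden("`attributable` and `total` must be the same length (or total scalar).", "validation")
  }
  mean(attributable / total)
}

#' Percent change between two values
#'
#' `100 (v_end - v_start) / v_start`, the trend metric behind
#' "percent change, 1990-2019" columns. Report-layer output rounds
#' half-away-from-zero to 2 decimals ([round_half_up()]).
#'
#' @param v_start Baseline value(s), strictly positive.
#' @param v_end Final value(s).
#' @return Percent change (vectorized, unrounded).
#' @examples
#' percent_change(65478.5, 105037.38) # 60.42...
#' @export
percent_change <- function(v_start, v_end) {
  if (any(!is.finite(v_start)) || any(v_start <= 0)) {
    abort_craburden("Percent change is undefined for non-positive baseline values.", "undefined")
  }
  100 * (v_end - v_start) / v_start
}

#' Aggregate a burden table over strata
#'
#' Collapses a stratified burden table over the requested keys. `Number`
#' metrics (and their draws) sum exactly; `Rate` metrics are never averaged —
#' they are recomputed from summed numerators and denominators, which
#' requires a matching `population` table. Attempting to aggregate `Rate`
#' rows without populations, or `Percent` rows at all, is a metric-safety
#' error.
#'
#' @param burden Tibble with a `metric` column (`"Number"` or `"Rate"`),
#'   stratum columns, `val`, and optional draw columns. Rates are per
#'   100,000.
#' @param over Character vector of stratum columns to collapse (subset of
#'   `c("age_group", "sex", "location", "cause", "risk")`). Empty `over`
#'   returns the table unchanged.
#' @param population Tibble with the same stratum columns and a `population`
#'   column; required when `Rate` rows are aggregated.
#' @return The aggregated tibble.
#' @export
aggregate_burden <- function(burden, over, population = NULL) {
  allowed <- c("age_group", "sex", "location", "cause", "risk")
  if (!all(over %in% allowed)) {
    abort_craburden(
      sprintf("Can only aggregate over %s.", paste(allowed, collapse = ", ")),
      "validation"
    )
  }
  if (length(over) == 0L) {
    return(burden)
  }
  if (!all(over %in% names(burden))) {
    abort_craburden("Grouping keys missing from the burden table.", "validation")
  }
  if (!"metric" %in% names(burden)) {
    abort_craburden("Burden table needs a `metric` column.", "validation")
  }
  if (any(burden$metric == "Percent")) {
    abort_craburden("Percent metrics cannot be aggregated by summation.", "metric_safety")
  }

  dc <- draw_cols(burden)
  keys <- setdiff(names(burden), c(over, "val", "lower", "upper", dc, "population"))

  number <- dplyr::filter(burden, .data$metric == "Number")
  rate <- dplyr::filter(burden, .data$metric == "Rate")

  out <- list()
  if (nrow(number) > 0) {
    out$number <- number |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(c("val", dc)), sum),
        .groups = "drop"
      )
  }
  if (nrow(rate) > 0) {
    if (is.null(population)) {
      abort_craburden(
        "Rate metrics cannot be summed; supply `population` so rates are recomputed from counts.",
        "metric_safety"
      )
    }
    pop_keys <- intersect(names(population), setdiff(names(burden), c("val", "lower", "upper", dc, "metric", "measure", "cause", "risk")))
    rate <- dplyr::inner_join(rate, population, by = pop_keys)
    if (any(is.na(rate$population))) {
      abort_craburden("Missing population for some rate strata.", "join")
    }
    out$rate <- rate |>
      dplyr::mutate(dplyr::across(dplyr::all_of(c("val", dc)), ~ .x * .data$population / 1e5)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(c("val", dc)), sum),
        population = sum(.data$population),
        .groups = "drop"
      ) |>
      dplyr::mutate(dplyr::across(dplyr::all_of(c("val", dc)), ~ .x / .data$population * 1e5)) |>
      dplyr::select(-"population")
  }
  dplyr::bind_rows(out)
}

#' Published global cancer trend table (GBD 2019)
#'
#' Global estimates of cancer DALYs attributable to eleven level 2 risk
#' factors (and their combination) by sex, as published from the public GBD
#' 2019 Results Tool: DALY counts (thousands) and age-standardized DALY
#' rates (per 100,000) in 1990 and 2019 with the published percent-change
#' cells, plus the published age-standardized PAF (%) values. Point
#' estimates only; the published uncertainty intervals are draw-level and
#' not reconstructible from this table.
#'
#' @return A tibble with columns `risk`, `sex`, `dalys_1990`, `dalys_2019`,
#'   `dalys_pct_change`, `asdr_1990`, `asdr_2019`, `asdr_pct_change`,
#'   `paf_1990`, `paf_2019`.
#' @export
gbd2019_global_trends <- function() {
  path <- system.file("extdata", "gbd2019_global_trends.csv", package = "craburden")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
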