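#' Draw-level PAFs for every risk-outcome pair and stratum of a world
#'
#' Runs the PAF engine over a synthetic world: fits the stratum exposure
#' distribution from its (mean, SD) point estimate, resolves the pair's
#' TMREL against it (TMRELs are resolved once per stratum from the point
#' estimate and held fixed across draws), and evaluates the continuous PAF
#' integral for every exposure draw on a fixed Simpson grid — or the
#' discrete PAF sum for categorical risks. Per cause and stratum, the
#' independence-combined PAF across all risks affecting that cause is added
#' with `risk = "_combined"`. Point estimates are means of draws; 95% UIs
#' are draw percentiles.
#'
#' @param world A [generate_world()] result.
#' @param n_grid Simpson grid size for the draw-level quadrature.
#' @return A tibble with `risk`, `cause`, stratum columns, `val`, `lower`,
#'   `upper`, and draw columns, PAFs on the proportion scale.
#' @export
compute_pafs <- function(world, n_grid = 501L) {
  stopifnot(inherits(world, "cra_world"))
  config <- world$config
  dnames <- paste0("draw_", seq_len(config$draws))
  spec_of <- stats::setNames(config$risks, vapply(config$risks, `[[`, character(1), "name"))

  out <- list()
  for (pair in world$registry) {
    spec <- spec_of[[pair$risk]]
    rows <- dplyr::filter(world$exposure, .data$risk == pair$risk)

    if (pair$curve$form == "categorical") {
      exposed <- dplyr::filter(rows, .data$category == "exposed")
      r <- unname(pair$curve$category_rrs["exposed"])
      p_draws <- draw_matrix(exposed)
      paf_draws <- p_draws * (r - 1) / (1 + p_draws * (r - 1))
      res <- exposed[c("location", "year", "sex", "age_group")]
    } else {
      means <- dplyr::filter(rows, .data$metric == "mean")
      sds <- dplyr::filter(rows, .data$metric == "sd")
      m_draws <- draw_matrix(means)
      paf_draws <- matrix(NA_real_, nrow(means), config$draws)
      for (i in seq_len(nrow(means))) {
        dist_i <- fit_mom(means$val[i], sds$val[i], spec$family)
        tmrel_i <- resolve_tmrel(pair$tmrel, curve = pair$curve, dist = dist_i)
        paf_draws[i, ] <- .paf_continuous_draws(
          m_draws[i, ], sds$val[i], spec$family, dist_i$support,
          pair$curve, tmrel_i, n_grid = n_grid
        )
      }
      res <- means[c("location", "year", "sex", "age_group")]
    }
    res$risk <- pair$risk
    res$cause <- pair$cause
    res$val <- rowMeans(paf_draws)
    qs <- .row_quantiles(paf_draws, c(0.025, 0.975))
    res$lower <- qs[, 1]
    res$upper <- qs[, 2]
    res[dnames] <- as.data.frame(paf_draws)
    out[[paste(pair$risk, pair$cause)]] <- res
  }

  # independence-combined PAF per cause-stratum, draw by draw
  combined <- list()
  for (cause in config$causes) {
    tabs <- Filter(function(t) t$cause[1] == cause, out)
    if (length(tabs) == 0) next
    compl <- Reduce(`*`, lapply(tabs, function(t) 1 - draw_matrix(t)))
    res <- tabs[[1]][c("location", "year", "sex", "age_group")]
    res$risk <- "_combined"
    res$cause <- cause
    paf_draws <- 1 - compl
    res$val <- rowMeans(paf_draws)
    qs <- .row_quantiles(paf_draws, c(0.025, 0.975))
    res$lower <- qs[, 1]
    res$upper <- qs[, 2]
    res[dnames] <- as.data.frame(paf_draws)
    combined[[cause]] <- res
  }

  cols <- c("risk", "cause", "location", "year", "sex", "age_group",
            "val", "lower", "upper", dnames)
  as_tibble(dplyr::bind_rows(c(out, combined))[cols])
}

.row_quantiles <- function(m, probs) {
  t(apply(m, 1, stats::quantile, probs = probs, names = FALSE, type = 7))
}

#' Global attributable-burden trends by risk
#'
#' Aggregates attributable DALYs to global per-risk totals per year and
#' computes the percent change between the first and last year. With draw
#' columns present, the change is computed per draw; the point estimate is
#' the mean of draw-level changes and the UI its 2.5th/97.5th percentiles.
#'
#' @param attributable Output of [attributable_burden()] with a `risk`
#'   column.
#' @return A tibble with `risk`, `val_start`, `val_end`, `pct_change`,
#'   `lower`, `upper`.
#' @export
trend_table <- function(attributable) {
  years <- sort(unique(attributable$year))
  if (length(years) < 2) {
    abort_craburden("Need at least two years for a trend.", "undefined")
  }
  y0 <- years[1]
  y1 <- years[length(years)]
  tot <- aggregate_burden(attributable[attributable$year %in% c(y0, y1), ],
                          over = c("location", "sex", "age_group", "cause"))
  dc <- draw_cols(tot)
  risks <- unique(tot$risk)
  rows <- lapply(risks, function(r) {
    a <- tot[tot$risk == r & tot$year == y0, ]
    b <- tot[tot$risk == r & tot$year == y1, ]
    if (nrow(a) != 1 || nrow(b) != 1) {
      abort_craburden(sprintf("Risk '%s' lacks a total for both years.", r), "undefined")
    }
    if (length(dc) > 0) {
      pc_draws <- percent_change(as.numeric(a[1, dc]), as.numeric(b[1, dc]))
      ui <- ui_from_draws(pc_draws)
      tibble(risk = r, val_start = a$val, val_end = b$val,
             pct_change = ui[["point"]], lower = ui[["lower"]], upper = ui[["upper"]])
    } else {
      tibble(risk = r, val_start = a$val, val_end = b$val,
             pct_change = percent_change(a$val, b$val),
             lower = NA_real_, upper = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}

# per-location all-age PAF for one risk in one year: attributable over the
# risk's causes divided by total burden over all causes
.location_pafs <- function(attributable, burden, risk, year) {
  att <- attributable[attributable$risk == risk & attributable$year == year, ]
  num <- att |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(att = sum(.data$val), .groups = "drop")
  den <- burden[burden$year == year, ] |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(total = sum(.data$val), .groups = "drop")
  dplyr::inner_join(num, den, by = "location") |>
    dplyr::mutate(paf = .data$att / .data$total)
}

#' Run the full comparative-risk-assessment pipeline
#'
#' Generates (or accepts) a synthetic world, computes draw-level PAFs and
#' attributable DALYs, global trend metrics, age-standardized attributable
#' DALY rates, SDI quintiles, PAF-SDI Spearman correlations, and the
#' loess-smoothed expected-PAF-by-SDI curve. When `out_dir` is given, all
#' tables are written as CSV (PAFs as `Percent` on the 0-100 scale,
#' attributable DALYs as `Number`, in the GBD-results dialect) together with
#' a JSON-lines log recording the seed, package version, and row counts.
#' Re-running with the same configuration reproduces every output file
#' byte for byte.
#'
#' @param config A [world_config()], a plain list of `world_config()`
#'   arguments (risks as lists of [risk_spec()] arguments), or the path to a
#'   YAML file holding such a list.
#' @param out_dir Optional output directory; created if absent.
#' @return Invisibly, a list with `world`, `pafs`, `attributable`, `trends`,
#'   `asdr`, `sdi_quintiles`, `sdi_correlations`, `expected_paf`, and
#'   `paths` (when written).
#' @export
run_pipeline <- function(config = world_config(), out_dir = NULL) {
  config <- .as_world_config(config)
  world <- generate_world(config)
  pafs <- compute_pafs(world)
  attributable <- attributable_burden(pafs, world$burden)
  trends <- trend_table(attributable)

  # age-standardized attributable DALY rate per location-risk-year
  std <- default_standard_population(config$age_groups)
  att_strat <- aggregate_burden(attributable, over = "cause")
  asdr <- att_strat |>
    dplyr::select(dplyr::all_of(c("risk", "location", "year", "sex", "age_group", "val"))) |>
    dplyr::inner_join(world$population, by = c("location", "year", "sex", "age_group")) |>
    dplyr::group_by(.data$risk, .data$location, .data$year, .data$age_group) |>
    dplyr::summarise(val = sum(.data$val), population = sum(.data$population), .groups = "drop") |>
    dplyr::mutate(rate = .data$val / .data$population * 1e5) |>
    dplyr::group_by(.data$risk, .data$location, .data$year) |>
    dplyr::summarise(
      asdr = age_standardize(stats::setNames(.data$rate, .data$age_group), std),
      .groups = "drop"
    )

  # SDI analysis in the reference (latest) year
  year_ref <- max(config$years)
  sdi_ref <- world$sdi[world$sdi$year == year_ref, ]
  quintiles <- assign_sdi_quintiles(sdi_ref$sdi, sdi_ref$location)
  risks_all <- unique(pafs$risk)
  correlations <- dplyr::bind_rows(lapply(risks_all, function(r) {
    lp <- .location_pafs(attributable, world$burden, r, year_ref)
    lp <- dplyr::inner_join(lp, sdi_ref[c("location", "sdi")], by = "location")
    ct <- spearman_paf_sdi(lp$paf, lp$sdi)
    tibble(risk = r, rho = ct$rho, p_value = ct$p_value, n = ct$n)
  }))
  expected <- NULL
  if (config$n_locations >= 10) {
    lp <- .location_pafs(attributable, world$burden, "_combined", year_ref)
    lp <- dplyr::inner_join(lp, sdi_ref[c("location", "sdi")], by = "location")
    expected <- expected_paf_curve(lp$paf, lp$sdi)
  }

  result <- list(
    world = world, pafs = pafs, attributable = attributable, trends = trends,
    asdr = asdr, sdi_quintiles = quintiles, sdi_correlations = correlations,
    expected_paf = expected
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    slim <- function(tbl) tbl[setdiff(names(tbl), draw_cols(tbl))]
    paths <- c(
      exposure = file.path(out_dir, "exposure.csv"),
      paf = file.path(out_dir, "paf.csv"),
      attributable = file.path(out_dir, "attributable_dalys.csv"),
      trends = file.path(out_dir, "trends.csv"),
      asdr = file.path(out_dir, "asdr.csv"),
      sdi = file.path(out_dir, "sdi_quintiles.csv"),
      correlations = file.path(out_dir, "sdi_correlations.csv")
    )
    readr::write_csv(slim(world$exposure), paths[["exposure"]], progress = FALSE)
    write_gbd_results(as_gbd_rows(slim(pafs), "DALYs (PAF)", "Percent"), paths[["paf"]])
    write_gbd_results(as_gbd_rows(slim(attributable), "DALYs", "Number"), paths[["attributable"]])
    readr::write_csv(trends, paths[["trends"]], progress = FALSE)
    readr::write_csv(asdr, paths[["asdr"]], progress = FALSE)
    readr::write_csv(quintiles, paths[["sdi"]], progress = FALSE)
    readr::write_csv(correlations, paths[["correlations"]], progress = FALSE)
    if (!is.null(expected)) {
      paths[["expected_paf"]] <- file.path(out_dir, "expected_paf_curve.csv")
      readr::write_csv(expected, paths[["expected_paf"]], progress = FALSE)
    }
    log_path <- file.path(out_dir, "pipeline_log.jsonl")
    log_lines <- c(
      jsonlite::toJSON(list(event = "config", seed = config$seed, draws = config$draws,
                            package_version = as.character(utils::packageVersion("craburden"))),
                       auto_unbox = TRUE),
      vapply(names(paths), function(nm) {
        n <- length(readr::read_lines(paths[[nm]], progress = FALSE)) - 1L
        as.character(jsonlite::toJSON(list(event = "written", table = nm, rows = n),
                                      auto_unbox = TRUE))
      }, character(1))
    )
    writeLines(log_lines, log_path)
    result$paths <- c(paths, log = log_path)
  }
  invisible(result)
}

.as_world_config <- function(config) {
  if (inherits(config, "world_config")) {
    return(config)
  }
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort_craburden("`config` must be a world_config, a list, or a YAML path.", "config")
  }
  if (!is.null(config$risks)) {
    config$risks <- lapply(config$risks, function(r) {
      if (inherits(r, "risk_spec")) r else do.call(risk_spec, lapply(r, .unlist_named))
    })
  }
  do.call(world_config, config)
}

# YAML maps arrive as lists; named numeric vectors (beta, rr_exposed) need
# flattening back
.unlist_named <- function(x) {
  if (is.list(x) && length(x) > 0 && !is.null(names(x)) && all(vapply(x, is.numeric, logical(1)))) {
    unlist(x)
  } else {
    x
  }
}
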