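test_that("world generation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$exposure, w2$exposure)
  expect_identical(w1$burden, w2$burden)
  expect_identical(w1$sdi, w2$sdi)
  expect_identical(w1$ground_truth$true_paf, w2$ground_truth$true_paf)
  # a different seed genuinely changes the data
  w3 <- generate_world(world_config(n_locations = 6, draws = 40, seed = 102))
  expect_false(identical(w1$exposure$val, w3$exposure$val))
})

test_that("configuration validation rejects malformed worlds", {
  expect_error(world_config(n_locations = 0), class = "craburden_error_config")
  expect_error(world_config(draws = 0), class = "craburden_error_config")
  expect_error(world_config(age_groups = c("40-44", "42-49")), class = "craburden_error_config")
  expect_error(world_config(age_groups = c("45-49", "40-44")), class = "craburden_error_config")
  expect_error(world_config(sexes = "Other"), class = "craburden_error_config")
  # a risk referencing an unknown cause is named in the failure
  bad <- risk_spec("solo", kind = "categorical_harmful", causes = "nonexistent_cancer",
                   prevalence_base = 0.2, rr_exposed = c(nonexistent_cancer = 2))
  expect_error(world_config(risks = list(bad)), "solo", class = "craburden_error_config")
})

test_that("point-mass exposure at the TMREL yields all-zero true PAFs", {
  pm <- risk_spec("pinned", kind = "continuous_harmful", causes = "lung_cancer",
                  family = "lognormal", mean_base = 0, sd_ratio = 0,
                  beta = c(lung_cancer = 0.02), sdi_effect = 0, sex_shift = 0,
                  year_drift = 0, age_amplitude = 0)
  w <- generate_world(world_config(n_locations = 3, draws = 5, risks = list(pm)))
  expect_true(all(w$ground_truth$true_paf$true_paf == 0))

  # same counterfactual-equals-factual contract for zero prevalence
  p0 <- risk_spec("never", kind = "categorical_harmful", causes = "lung_cancer",
                  prevalence_base = 0, rr_exposed = c(lung_cancer = 2.5),
                  sdi_effect = 0, sex_shift = 0, year_drift = 0, age_amplitude = 0)
  w0 <- generate_world(world_config(n_locations = 3, draws = 5, risks = list(p0)))
  expect_true(all(w0$ground_truth$true_paf$true_paf == 0))
})

test_that("dichotomous ground truth follows the closed form p(r-1)/(1+p(r-1))", {
  spec <- risk_spec("half", kind = "categorical_harmful", causes = "lung_cancer",
                    prevalence_base = 0.5, rr_exposed = c(lung_cancer = 2),
                    sdi_effect = 0, sex_shift = 0, year_drift = 0, age_amplitude = 0)
  w <- generate_world(world_config(n_locations = 2, draws = 5, risks = list(spec)))
  tp <- w$ground_truth$true_paf
  expect_true(all(abs(tp$true_paf[tp$risk == "half"] - 1 / 3) < 1e-12))
})

test_that("generated exposures carry the configured SDI rank correlation", {
  spec <- risk_spec("smoke", kind = "categorical_harmful", causes = "lung_cancer",
                    prevalence_base = 0.3, rr_exposed = c(lung_cancer = 2.5),
                    sdi_rho = 0.8, sdi_effect = 0.8, sex_shift = 0,
                    year_drift = 0, age_amplitude = 0)
  w <- generate_world(world_config(n_locations = 100, draws = 2, risks = list(spec), seed = 7))
  prev <- dplyr::filter(w$exposure, .data$category == "exposed",
                        .data$year == 1990, .data$sex == "Male",
                        .data$age_group == "40-44")
  sdi <- dplyr::filter(w$sdi, .data$year == 1990)
  rho <- spearman_paf_sdi(prev$val[match(sdi$location, prev$location)], sdi$sdi)$rho
  # Gaussian-copula target ~ (6/pi) asin(0.8/2) = 0.786; n = 100 so
  # Monte-Carlo error is about 1/sqrt(n-1) = 0.1
  expect_gt(rho, 0.786 - 3 * 0.1)
  expect_lt(rho, min(1, 0.786 + 3 * 0.1))
})

test_that("true attributable burden equals true PAF times total DALYs exactly", {
  w <- generate_world(tiny_config())
  tp <- w$ground_truth$true_paf
  j <- dplyr::inner_join(
    tp, w$burden[c("cause", "location", "year", "sex", "age_group", "val")],
    by = c("cause", "location", "year", "sex", "age_group")
  )
  expect_identical(j$true_attributable, j$true_paf * j$val)
})

test_that("ground-truth lookup returns the recorded PAF and rejects unknown strata", {
  w <- generate_world(tiny_config())
  row <- w$ground_truth$true_paf[1, ]
  expect_equal(
    ground_truth_paf(w$ground_truth, row$risk, row$cause, row$location,
                     row$year, row$sex, row$age_group),
    row$true_paf
  )
  expect_error(
    ground_truth_paf(w$ground_truth, "no_such_risk", row$cause, row$location,
                     row$year, row$sex, row$age_group),
    class = "craburden_error_lookup"
  )
})

test_that("generator quadrature matches a sampling oracle for continuous truths", {
  # the generator-side trapezoid is an independent path; check it against
  # plain Monte-Carlo sampling of the same lognormal exposure
  withr::local_seed(701)
  mean <- 27
  sd <- 4
  beta <- log(1.02)
  d <- fit_mom(mean, sd, "lognormal")
  x <- exposure_sample(d, 5e5)
  paf_mc <- (mean(exp(beta * x)) - 1) / mean(exp(beta * x))
  truth <- craburden:::.truth_paf_continuous("lognormal", mean, sd, beta, protective = FALSE)
  expect_lt(abs(truth - paf_mc), 0.003)
})
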