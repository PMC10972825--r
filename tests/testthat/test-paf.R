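harmful_curve <- function(beta = 0.02) {
  rr_curve("r", "c", form = "log_linear", beta = beta,
           shape = "monotone_increasing", reference = 0)
}

test_that("continuous PAF closed forms: point masses and factual-equals-counterfactual", {
  curve <- harmful_curve()
  # all mass at the TMREL: nothing to attribute
  expect_equal(paf_continuous(fit_mom(0, 0), curve, tmrel = 0), 0)
  expect_equal(paf_continuous(fit_mom(7, 0), curve, tmrel = 7), 0)
  # point mass with RR(x*) = 2 against RR(tmrel) = 1 gives (2-1)/2
  x_star <- log(2) / 0.02
  expect_equal(paf_continuous(fit_mom(x_star, 0), curve, tmrel = 0), 0.5,
               tolerance = 1e-12)
})

test_that("a categorical mixture of point masses matches the discrete formula", {
  withr::local_seed(402)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    p <- as.numeric(stats::rmultinom(1, 1000, runif(k)) / 1000)
    vals <- sort(runif(k, 0, 60))
    curve <- harmful_curve(runif(1, 0.005, 0.04))
    dist <- categorical_exposure(paste0("c", 1:k), p, values = vals)
    rrs <- rr_at(curve, vals)
    expect_equal(
      paf_continuous(dist, curve, tmrel = vals[1]),
      paf_discrete(p, rrs, 1),
      tolerance = 1e-9
    )
  }
})

test_that("discrete PAF reproduces hand-computed values and validates input", {
  expect_equal(paf_discrete(c(0.5, 0.5), c(1, 2), 1), 1 / 3, tolerance = 1e-12)
  expect_equal(paf_discrete(c(1, 0), c(1, 2), 1), 0)
  expect_equal(paf_discrete(c(0.2, 0.3, 0.5), c(1, 1.5, 3), 1),
               (0.2 + 0.45 + 1.5 - 1) / 2.15, tolerance = 1e-12)
  expect_error(paf_discrete(c(0.6, 0.5), c(1, 2), 1), class = "craburden_error_validation")
  expect_error(paf_discrete(c(0.5, 0.5), c(1, -2), 1), class = "craburden_error_validation")
  expect_error(paf_discrete(c(0.5, 0.5), c(1, 2), 3), class = "craburden_error_validation")
})

test_that("quadrature PAF agrees with a Monte-Carlo cohort oracle", {
  withr::local_seed(403)
  for (i in 1:5) {
    tri <- random_paf_triple()
    paf_q <- paf_continuous(tri$dist, tri$curve, tri$tmrel)
    mc <- mc_paf_oracle(tri$dist, tri$curve, tri$tmrel, n = 2e5)
    expect_lt(abs(paf_q - mc$paf), 3 * mc$se + 1e-6)
  }
})

test_that("negative PAFs are returned for populations below the counterfactual", {
  protective <- rr_curve("r", "c", form = "log_linear", beta = -0.01,
                         shape = "monotone_decreasing", reference = 0)
  d <- fit_mom(100, 10, "normal")
  # counterfactual at an exposure *below* the population: RR(tmrel) > mean RR
  paf <- paf_continuous(d, protective, tmrel = 50)
  expect_lt(paf, 0)
})

test_that("PAF combination is multiplicative, order-invariant, and bounded", {
  expect_equal(combine_pafs(0.5), 0.5)
  expect_equal(combine_pafs(c(0.5, 0.5)), 0.75)
  withr::local_seed(404)
  for (i in 1:25) {
    p <- runif(sample(2:6, 1))
    comb <- combine_pafs(p)
    expect_equal(comb, combine_pafs(rev(p)), tolerance = 1e-15)
    expect_lte(comb, 1)
    expect_gte(comb, max(p) - 1e-15)
  }
  expect_error(combine_pafs(c(0.5, 1.2)), class = "craburden_error_validation")
})

test_that("uncertainty intervals follow the pinned percentile rule", {
  expect_equal(ui_from_draws(c(5, 5, 5, 5)), c(lower = 5, upper = 5, point = 5))
  ui <- ui_from_draws(1:1000)
  expect_equal(ui[["lower"]], 25.975, tolerance = 1e-9)
  expect_equal(ui[["upper"]], 975.025, tolerance = 1e-9)
  expect_equal(ui[["point"]], 500.5)
  # symmetric draws: point sits midway between the bounds
  withr::local_seed(405)
  z <- rnorm(501)
  z <- c(z, -z) # exactly symmetric around 0
  ui <- ui_from_draws(z)
  expect_equal(ui[["point"]], (ui[["lower"]] + ui[["upper"]]) / 2, tolerance = 1e-9)
  expect_error(ui_from_draws(5), class = "craburden_error_draws")
})

test_that("attributable burden multiplies draw-wise and conserves the total", {
  paf <- tibble::tibble(
    risk = "r", cause = "c", location = "loc", year = 2019,
    val = 0.15, draw_1 = 0.1, draw_2 = 0.2
  )
  burden <- tibble::tibble(
    cause = "c", location = "loc", year = 2019, metric = "Number",
    val = 100, draw_1 = 100, draw_2 = 100
  )
  att <- attributable_burden(paf, burden)
  expect_equal(att$draw_1, 10)
  expect_equal(att$draw_2, 20)
  expect_equal(att$val, 15) # mean of attributable draws

  # conservation: attributable + (1 - PAF) x total = total, draw by draw
  compl <- (1 - c(0.1, 0.2)) * c(100, 100)
  expect_equal(c(att$draw_1, att$draw_2) + compl, c(100, 100), tolerance = 1e-12)

  # zero PAF gives zero attributable burden
  paf0 <- dplyr::mutate(paf, val = 0, draw_1 = 0, draw_2 = 0)
  expect_equal(attributable_burden(paf0, burden)$val, 0)

  # unmatched strata are a join error naming the keys
  paf_bad <- dplyr::mutate(paf, cause = "nope")
  expect_error(attributable_burden(paf_bad, burden), class = "craburden_error_join")
})
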