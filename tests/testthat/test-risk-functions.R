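test_that("category-level RRs convert to the per-unit log-RR slope", {
  # 17% higher risk per 50 g (processed-meat-like): midpoints 25 g and 75 g
  expect_equal(category_to_per_unit(c(25, 75), c(1.17, 1.17^2)), log(1.17) / 50,
               tolerance = 1e-12)
  # 18% per 100 g (red-meat-like)
  expect_equal(category_to_per_unit(c(50, 150), c(1.18, 1.18^2)), log(1.18) / 100,
               tolerance = 1e-12)
  # flat RRs give a zero slope
  expect_equal(category_to_per_unit(c(10, 20, 30), c(1, 1, 1)), 0)
  # interval bounds: midpoints are used
  expect_equal(
    category_to_per_unit(cbind(c(0, 50), c(50, 100)), c(1.17, 1.17^2)),
    log(1.17) / 50,
    tolerance = 1e-12
  )
  expect_error(category_to_per_unit(25, 1.17), class = "craburden_error_conversion")
  expect_error(category_to_per_unit(c(25, 75), c(1.17, -2)), class = "craburden_error_conversion")
})

test_that("log-linear curves evaluate and compose multiplicatively", {
  meat <- rr_curve("meat", "crc",
    form = "log_linear", beta = log(1.17) / 50,
    shape = "monotone_increasing", reference = 0
  )
  expect_equal(rr_at(meat, 0), 1)
  expect_equal(rr_at(meat, 50), 1.17, tolerance = 1e-12)
  expect_equal(rr_at(meat, 100), exp(2 * log(1.17)), tolerance = 1e-12)

  withr::local_seed(31)
  for (i in 1:20) {
    x1 <- runif(1, 0, 100)
    x2 <- runif(1, 0, 100)
    expect_equal(rr_at(meat, x1 + x2), rr_at(meat, x1) * rr_at(meat, x2),
                 tolerance = 1e-12)
  }
})

test_that("tabulated curves interpolate through knots and clamp beyond them", {
  curve <- rr_curve("r", "c",
    form = "tabulated_monotone", shape = "monotone_increasing",
    knots = c(0, 1, 2, 4), values = c(1, 1.3, 1.8, 2.1)
  )
  expect_equal(rr_at(curve, c(0, 1, 2, 4)), c(1, 1.3, 1.8, 2.1), tolerance = 1e-9)
  # monotone between knots
  grid <- seq(0, 4, length.out = 200)
  expect_true(all(diff(rr_at(curve, grid)) >= -1e-12))
  # constant extrapolation
  expect_equal(rr_at(curve, 10), 2.1, tolerance = 1e-9)
  expect_equal(rr_at(curve, -5), 1, tolerance = 1e-9)
})

test_that("declared shapes are verified at construction", {
  expect_error(
    rr_curve("r", "c", form = "log_linear", beta = -0.1, shape = "monotone_increasing"),
    class = "craburden_error_shape"
  )
  expect_error(
    rr_curve("r", "c",
      form = "tabulated_monotone", shape = "monotone_decreasing",
      knots = c(0, 1, 2), values = c(1, 1.2, 1.5)
    ),
    class = "craburden_error_shape"
  )
  # inverted-V (interior nadir) accepted only with a genuine nadir
  ok <- rr_curve("r", "c",
    form = "tabulated_monotone", shape = "inverted_V",
    knots = c(0, 1, 3, 5), values = c(1.5, 1.2, 1, 1.4), reference = 3
  )
  expect_s3_class(ok, "rr_curve")
  expect_error(
    rr_curve("r", "c",
      form = "tabulated_monotone", shape = "inverted_V",
      knots = c(0, 1, 3), values = c(1, 1.2, 1.5), reference = 0
    ),
    class = "craburden_error_shape"
  )
})

test_that("TMREL rules resolve per curve shape and exposure distribution", {
  harmful <- rr_curve("r", "c",
    form = "log_linear", beta = 0.02,
    shape = "monotone_increasing", reference = 0
  )
  expect_equal(resolve_tmrel(tmrel_spec("fixed_zero"), harmful), 0)

  vshape <- rr_curve("r", "c",
    form = "tabulated_monotone", shape = "inverted_V",
    knots = c(0, 1, 3, 5), values = c(1.5, 1.2, 1, 1.4), reference = 3
  )
  expect_equal(resolve_tmrel(tmrel_spec("nadir"), vshape), 3, tolerance = 1e-3)

  protective <- rr_curve("r", "c",
    form = "log_linear", beta = -0.01,
    shape = "monotone_decreasing", reference = 0
  )
  d <- fit_mom(100, 10, "normal")
  expect_equal(resolve_tmrel(tmrel_spec("percentile_85"), protective, d),
               110.364, tolerance = 1e-3)

  expect_error(resolve_tmrel(tmrel_spec("nadir"), harmful),
               class = "craburden_error_shape")
  expect_error(resolve_tmrel(tmrel_spec("percentile_85"), protective),
               class = "craburden_error_tmrel")
})

test_that("nadir ties break toward the lowest exposure", {
  flat_bottom <- rr_curve("r", "c",
    form = "tabulated_monotone", shape = "inverted_V",
    knots = c(0, 1, 2, 3, 4), values = c(1.4, 1, 1, 1, 1.5), reference = 1
  )
  expect_equal(resolve_tmrel(tmrel_spec("nadir"), flat_bottom), 1, tolerance = 1e-3)
})

test_that("the registry rejects duplicate pairs and flags inconsistent TMRELs", {
  curve <- rr_curve("r", "c",
    form = "log_linear", beta = 0.02,
    shape = "monotone_increasing", reference = 0
  )
  p1 <- risk_outcome_pair("r", "c", curve, tmrel_spec("fixed_zero"))
  expect_error(risk_registry(list(p1, p1)), class = "craburden_error_registry")

  # a TMREL strictly above the curve minimum is suspicious and warned about
  expect_warning(
    risk_outcome_pair("r", "c", curve, tmrel_spec("explicit_value", value = 10)),
    "not the curve minimum"
  )
})
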