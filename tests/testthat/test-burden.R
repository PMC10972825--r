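test_that("direct age-standardization is a weighted sum with full coverage", {
  std <- standard_population(c("40-44", "45-49"), c(0.6, 0.4))
  expect_equal(age_standardize(c("40-44" = 100, "45-49" = 200), std), 140)
  expect_equal(age_standardize(c("40-44" = 7, "45-49" = 7), std), 7)
  expect_equal(age_standardize(c("40-44" = 0, "45-49" = 0), std), 0)
  expect_error(age_standardize(c("40-44" = 100), std), class = "craburden_error_coverage")
  expect_error(standard_population(c("a", "b"), c(1, -1)), class = "craburden_error_validation")
})

test_that("ASR equals the crude rate when the age structure matches the standard", {
  withr::local_seed(501)
  ages <- paste0("a", 1:6)
  w <- runif(6)
  w <- w / sum(w)
  std <- standard_population(ages, w)
  rates <- stats::setNames(runif(6, 50, 500), ages)
  pop <- 1e5 * w # population structured exactly like the standard
  crude <- sum(rates * pop) / sum(pop)
  expect_equal(age_standardize(rates, std), crude, tolerance = 1e-12)
  # invariant to uniform population scaling (weights are proportions)
  std2 <- standard_population(ages, w * 1e7)
  expect_equal(age_standardize(rates, std2), age_standardize(rates, std), tolerance = 1e-12)
})

test_that("PAF from burden is the draw-wise ratio, averaged", {
  expect_equal(paf_from_burden(0, 1000), 0)
  expect_equal(paf_from_burden(250, 1000), 0.25)
  expect_equal(paf_from_burden(c(10, 30), c(100, 100)), 0.2)
  # with unequal denominators the draw-wise mean differs from ratio-of-means
  expect_equal(paf_from_burden(c(10, 30), c(100, 50)), 0.35)
  expect_false(isTRUE(all.equal(0.35, (10 + 30) / (100 + 50))))
  expect_error(paf_from_burden(10, 0), class = "craburden_error_undefined")
})

test_that("percent change reproduces published trend cells and its inverse identity", {
  expect_equal(round_half_up(percent_change(65478.5, 105037.38), 2), 60.42)
  expect_equal(round_half_up(percent_change(40262.81, 59323.57), 2), 47.34)
  expect_equal(percent_change(123.45, 123.45), 0)
  withr::local_seed(502)
  for (i in 1:10) {
    a <- runif(1, 1, 100)
    b <- runif(1, 1, 100)
    expect_equal(1 + percent_change(a, b) / 100, b / a, tolerance = 1e-12)
  }
  expect_error(percent_change(0, 10), class = "craburden_error_undefined")
  expect_error(percent_change(-5, 10), class = "craburden_error_undefined")
})

test_that("published global trend cells recompute from printed inputs", {
  t1 <- gbd2019_global_trends()
  pc_dalys <- round_half_up(percent_change(t1$dalys_1990, t1$dalys_2019), 2)
  pc_asdr <- round_half_up(percent_change(t1$asdr_1990, t1$asdr_2019), 2)
  # printed inputs carry 2-dp rounding, so recomputed cells can drift by a
  # few hundredths of a percentage point; they must never drift more
  expect_true(all(abs(pc_dalys - t1$dalys_pct_change) <= 0.05))
  expect_true(all(abs(pc_asdr - t1$asdr_pct_change) <= 0.05))
  # and the large majority of DALY-count cells agree exactly at 2 dp
  expect_gte(mean(pc_dalys == t1$dalys_pct_change), 0.9)
})

test_that("aggregation sums Numbers, pools Rates via counts, and refuses unsafe sums", {
  number <- tibble::tibble(
    measure = "DALYs", cause = "all", location = "Global", year = 2019,
    sex = c("Male", "Female"), age_group = "All ages", metric = "Number",
    val = c(67474, 37563.38), draw_1 = c(1, 2), draw_2 = c(3, 4)
  )
  agg <- aggregate_burden(number, over = "sex")
  expect_equal(agg$val, 105037.38)
  expect_equal(agg$draw_1, 3)
  expect_equal(agg$draw_2, 7)

  # empty `over` is the identity
  expect_identical(aggregate_burden(number, character(0)), number)

  # pooled rates come from summed counts: {10, 30} per 100k with populations
  # {100k, 300k} pool to 25, not the naive mean 20
  rate <- tibble::tibble(
    measure = "DALYs", cause = "all", location = c("A", "B"), year = 2019,
    sex = "Both", age_group = "All ages", metric = "Rate", val = c(10, 30)
  )
  pop <- tibble::tibble(
    location = c("A", "B"), year = 2019, sex = "Both", age_group = "All ages",
    population = c(1e5, 3e5)
  )
  pooled <- aggregate_burden(rate, over = "location", population = pop)
  expect_equal(pooled$val, 25)

  expect_error(aggregate_burden(rate, over = "location"),
               class = "craburden_error_metric_safety")
  pct <- dplyr::mutate(rate, metric = "Percent")
  expect_error(aggregate_burden(pct, over = "location"),
               class = "craburden_error_metric_safety")
})

test_that("aggregation is associative across grouping steps", {
  withr::local_seed(503)
  tbl <- tidyr::expand_grid(
    measure = "DALYs", cause = c("c1", "c2"), location = "L",
    year = 2019, sex = c("Male", "Female"), age_group = paste0("a", 1:3),
    metric = "Number"
  )
  tbl$val <- runif(nrow(tbl), 10, 100)
  one_step <- aggregate_burden(tbl, over = c("sex", "age_group"))
  two_step <- aggregate_burden(aggregate_burden(tbl, over = "sex"), over = "age_group")
  expect_equal(
    dplyr::arrange(one_step, cause)$val,
    dplyr::arrange(two_step, cause)$val,
    tolerance = 1e-12
  )
})
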