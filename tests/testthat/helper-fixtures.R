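# Shared fixtures: all built in code at test time.

# a small but fully structured world for module tests
tiny_config <- function(...) {
  world_config(n_locations = 6, draws = 40, seed = 101, ...)
}

# random (exposure distribution, RR curve, tmrel) triple for oracle checks;
# relies on the caller having fixed the RNG seed
random_paf_triple <- function() {
  family <- sample(c("normal", "lognormal", "gamma"), 1)
  mean <- runif(1, 5, 50)
  sd <- mean * runif(1, 0.1, 0.3)
  protective <- runif(1) < 0.3
  use_tabulated <- runif(1) < 0.3
  dist <- fit_mom(mean, sd, family)
  if (use_tabulated) {
    # monotone increasing tabulated curve over the support, RR = 1 at l
    kn <- seq(dist$support[1], dist$support[2], length.out = 6)
    slope <- runif(1, 0.005, 0.03)
    curve <- rr_curve("r", "c",
      form = "tabulated_monotone", shape = "monotone_increasing",
      knots = kn, values = exp(slope * (kn - kn[1])), reference = kn[1]
    )
    tmrel <- kn[1]
  } else if (protective) {
    curve <- rr_curve("r", "c",
      form = "log_linear", beta = -runif(1, 0.005, 0.03),
      shape = "monotone_decreasing", reference = 0
    )
    tmrel <- exposure_quantile(dist, 0.85)
  } else {
    curve <- rr_curve("r", "c",
      form = "log_linear", beta = runif(1, 0.005, 0.03),
      shape = "monotone_increasing", reference = 0
    )
    tmrel <- 0
  }
  list(dist = dist, curve = curve, tmrel = tmrel)
}

# Monte-Carlo cohort oracle for the continuous PAF: sample exposures, average
# the relative risk, apply the formula; returns the estimate and its delta-
# method standard error
mc_paf_oracle <- function(dist, curve, tmrel, n = 1e6) {
  x <- exposure_sample(dist, n)
  rr <- rr_at(curve, x)
  rr_t <- rr_at(curve, tmrel)
  mean_rr <- mean(rr)
  se_mean <- stats::sd(rr) / sqrt(n)
  list(
    paf = (mean_rr - rr_t) / mean_rr,
    se = rr_t * se_mean / mean_rr^2
  )
}

# independent Spearman oracle: explicit double-argsort ranks + textbook
# Pearson sum formula (no cor(), no rank())
brute_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    r[order(v)] <- seq_along(v)
    r
  }
  rx <- rk(x)
  ry <- rk(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}
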