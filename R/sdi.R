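#' Sociodemographic index
#'
#' The SDI is the geometric mean of three 0-1 indices — total fertility under
#' age 25 (inverted so that higher is better), mean education among those 15
#' and older, and lag-distributed income per capita — multiplied by 100 to
#' range from 0 (worst) to 100 (best). The composite is invariant to the
#' order of its components, and is 0 whenever any component is 0.
#'
#' @param tfu25,edu15,ldi Component indices in `[0, 1]` (vectorized).
#' @return SDI values in `[0, 100]`.
#' @examples
#' compute_sdi(0.5, 0.5, 0.5) # 50
#' @export
compute_sdi <- function(tfu25, edu15, ldi) {
  comp <- cbind(tfu25, edu15, ldi)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 1)) {
    abort_craburden("SDI components must lie in [0, 1].", "validation")
  }
  100 * (tfu25 * edu15 * ldi)^(1 / 3)
}

#' Assign SDI quintiles
#'
#' Locations are ranked by SDI and split into five equal-count quintiles
#' (low, low-middle, middle, high-middle, high). The k-th quintile boundary
#' sits at rank `round(n k / 5)` (half-away-from-zero), so 204 locations
#' split at ranks 41 / 82 / 122 / 163. Ties in SDI are broken by location
#' identifier order, making the assignment deterministic.
#'
#' @param sdi Numeric SDI per location.
#' @param locations Location identifiers (same length as `sdi`).
#' @return A tibble with `location`, `sdi`, and an ordered factor `quintile`.
#' @export
assign_sdi_quintiles <- function(sdi, locations) {
  if (length(sdi) != length(locations)) {
    abort_craburden("`sdi` and `locations` must have equal length.", "validation")
  }
  n <- length(sdi)
  if (n < 5L) {
    abort_craburden("Need at least 5 locations to form SDI quintiles.", "insufficient_data")
  }
  labels <- c("low", "low-middle", "middle", "high-middle", "high")
  ord <- order(sdi, as.character(locations))
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  bounds <- round_half_up(n * (1:5) / 5, 0)
  q <- vapply(rank_of, function(r) which(r <= bounds)[1], integer(1))
  tibble(
    location = locations, sdi = sdi,
    quintile = factor(labels[q], levels = labels, ordered = TRUE)
  )
}

#' Spearman rank correlation between PAF and SDI
#'
#' Spearman's rho with average ranks for ties. The two-sided p-value uses the
#' exact permutation null (all `n!` rank permutations) for `n <= 10` and the
#' large-sample t approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom otherwise. Significance is conventionally read at
#' p < 0.05.
#'
#' @param paf PAF per location.
#' @param sdi SDI per location (paired with `paf`).
#' @return A list with `rho`, `p_value`, and `n`.
#' @export
spearman_paf_sdi <- function(paf, sdi) {
  if (length(paf) != length(sdi)) {
    abort_craburden("`paf` and `sdi` must be paired vectors of equal length.", "pairing")
  }
  n <- length(paf)
  if (n < 4L) {
    abort_craburden("Need at least 4 paired observations.", "insufficient_data")
  }
  rx <- rank(paf)
  ry <- rank(sdi)
  rho <- stats::cor(rx, ry)
  p <- if (n <= 10L) {
    .spearman_perm_p(rx, ry, rho)
  } else {
    if (abs(rho) >= 1) {
      0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p_value = p, n = n)
}

# exact two-sided permutation p-value: share of the n! permutations whose
# |rho| reaches the observed |rho|; the null set of sums depends only on the
# two rank multisets, so it is cached per session
.spearman_null_cache <- new.env(parent = emptyenv())

.spearman_perm_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  key <- paste(c(n, sort(rx), sort(ry)), collapse = ",")
  rhos <- .spearman_null_cache[[key]]
  if (is.null(rhos)) {
    P <- .permutations(n)
    # rho for each permutation pi: cor(rx[pi], ry), standardized via sums
    s <- matrix(rx[P], nrow = nrow(P)) %*% ry
    mx <- mean(rx)
    my <- mean(ry)
    sx <- sqrt(sum((rx - mx)^2))
    sy <- sqrt(sum((ry - my)^2))
    rhos <- (as.numeric(s) - n * mx * my) / (sx * sy)
    .spearman_null_cache[[key]] <- rhos
  }
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# all permutations of 1..n as an n! x n integer matrix (insertion build)
.permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    blocks <- lapply(seq_len(k), function(j) {
      cbind(P[, seq_len(j - 1L), drop = FALSE],
            k,
            P[, seq_len(k - j) + (j - 1L), drop = FALSE])
    })
    P <- do.call(rbind, blocks)
  }
  P
}

#' Expected PAF as a smooth function of SDI
#'
#' Local linear regression (loess, degree 1, default span 0.5, direct
#' surface) of PAF on SDI, evaluated on a unit-step SDI grid spanning the
#' observed range. The smoother reproduces exactly linear PAF-SDI
#' relationships and returns a flat line for constant PAF; it summarises the
#' development gradient a full spatial model would capture, without
#' extrapolating beyond the observed SDI range.
#'
#' @param paf PAF per location.
#' @param sdi SDI per location.
#' @param span Loess span (fraction of points in each local fit).
#' @return A tibble with columns `sdi` (unit grid) and `expected_paf`.
#' @export
expected_paf_curve <- function(paf, sdi, span = 0.5) {
  if (length(paf) != length(sdi)) {
    abort_craburden("`paf` and `sdi` must be paired vectors of equal length.", "pairing")
  }
  if (length(paf) < 10L) {
    abort_craburden("Need at least 10 observations to smooth the expected PAF.", "insufficient_data")
  }
  fit <- stats::loess(paf ~ sdi,
    data = data.frame(paf = paf, sdi = sdi),
    span = span, degree = 1, family = "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  grid <- seq(ceiling(min(sdi)), floor(max(sdi)), by = 1)
  tibble(sdi = grid, expected_paf = as.numeric(stats::predict(fit, newdata = data.frame(sdi = grid))))
}
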