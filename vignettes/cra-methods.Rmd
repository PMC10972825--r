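---
title: "Comparative risk assessment with craburden: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative risk assessment with craburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craburden)
```

## The comparative risk assessment model

Comparative risk assessment quantifies the share of a disease's burden that
would disappear if population exposure to a risk factor were moved to its
theoretical minimum-risk exposure level (TMREL). Three objects define the
computation for each risk-outcome pair and population stratum (location,
year, sex, 5-year age band):

1. **An exposure distribution** `P(x)`. Stratum exposure is summarised as a
   mean and standard deviation, and `fit_mom()` recovers a parametric
   distribution from those two moments (normal, lognormal, or gamma; a zero
   SD degenerates to a point mass). Categorical exposures carry category
   prevalences instead. The integration support `[l, m]` defaults to six
   standard deviations around the mean, clipped to the family's natural
   range, and the density is renormalized over it.

2. **A relative-risk curve** `RR(x)` with `RR = 1` at its reference
   exposure. Log-linear curves (`exp(beta (x - reference))`) represent
   per-unit effect sizes converted from category-level studies by
   `category_to_per_unit()`, which regresses log RR on category midpoints —
   for example, a 17% risk increase per 50 g of intake corresponds to
   `beta = log(1.17)/50` per gram. Fitted non-linear dose-response curves
   are accepted as knot tables and interpolated shape-preservingly in
   log-RR; beyond the outermost knots the RR is held constant rather than
   extrapolated exponentially.

3. **A TMREL rule.** Harmful monotone-increasing risks use 0; curves with an
   interior nadir use the exposure at the nadir; protective
   monotone-decreasing risks (fruit-intake-like) use the 85th percentile of
   the stratum's exposure distribution. The declared curve shape is verified
   at construction, and a resolved TMREL whose RR is not the curve minimum
   triggers a warning, because the PAF formula subtracts `RR(TMREL)`
   exactly as given.

The continuous PAF is
`(∫ RR(x)P(x)dx − RR(TMREL)) / ∫ RR(x)P(x)dx` over the support, the
discrete PAF replaces integrals with prevalence-weighted sums, and
independent risks combine as `1 − ∏(1 − PAFᵢ)`. Attributable DALYs are
`PAF × total DALYs` per cause and stratum. All draw-level arithmetic is
performed per draw; point estimates are draw means and 95% uncertainty
intervals are the 2.5th/97.5th draw percentiles.

Negative PAFs are legitimate (a population on average below the
counterfactual risk level) and are returned unclipped; clipping is left to
the reporting layer.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| exposure support | mean ± 6 SD, clipped at 0 for non-negative families | exposure units | the PAF integral needs finite bounds; ±6 SD leaves negligible clipped mass while keeping `E[RR]` finite for log-linear curves with lognormal exposure (whose untruncated moment generating function diverges) |
| moment matching | pre-truncation | — | simple method-of-moments; with the default support the post-truncation moments differ negligibly, and the approximation is documented rather than hidden |
| TMREL percentile (protective risks) | 0.85 | probability | the standard protective-risk convention; resolved once per stratum from the point-estimate distribution and held fixed across draws |
| draws | 1000 | count | conventional draw count for burden pipelines; every stochastic path requires a seed |
| UI percentile rule | ranks `1 + (n−1)q`, linear interpolation | — | must be pinned for reproducibility; this rule makes draws `1..1000` yield the interval (25.975, 975.025) |
| quadrature | adaptive, absolute tolerance 1e-8; 2001-point Simpson fallback | — | the integral is given by the framework, not its numerics; point masses and categorical mixtures are handled analytically |
| draw-level quadrature grid | 501-point Simpson per stratum | — | draws share the stratum's support, so the quadrature becomes one matrix product; the grid error is orders of magnitude below draw noise |
| nadir search | 10,001-point grid, ties to lowest exposure | — | deterministic and resolution-documented |

## What the synthetic world emulates — and what it does not

`generate_world()` produces a self-contained, GBD-results-shaped dataset:
per-stratum exposure means/SDs (continuous) or prevalences (categorical)
with draw noise, per-cause baseline DALYs with multiplicative lognormal
draws, per-stratum populations, and an SDI table. One latent development
axis per location drives both the SDI components and — through a
configurable rank correlation (`sdi_rho`) — the exposure levels, so
PAF-versus-SDI analyses have a recoverable gradient. Mild age, sex, and
period structure is layered on top.

Draw-noise levels are fixed study conditions, chosen once: a 2% coefficient
of variation on continuous exposure means, 0.05 logit-SD on prevalences,
and a 10% CV on DALYs. These produce PAF uncertainty intervals a few
percentage points wide, comparable to published burden intervals, and are
deliberately not tuned per analysis.

Crucially, the generator records **ground-truth PAFs computed on its own
side** — a 4001-point trapezoid rule and closed forms, independent of the
engine's adaptive/Simpson path — so pipeline output can be checked for
parameter recovery rather than merely for self-consistency.

What the generator does *not* emulate: real-world joint distributions of
risks within individuals (risks are generated independently, exactly as the
multiplicative combination formula assumes), mediation between correlated
risks, country-calibrated demography, exposure lag times, and the
ensemble-distribution machinery of production burden pipelines. Passing
recovery tests therefore demonstrates that the engine inverts the
generating model correctly — not that any particular real-world extract
satisfies that model.

## Numerical and degenerate-input behaviour

* `sd = 0` always yields a point mass; its PAF is evaluated analytically,
  and a point mass at the TMREL gives exactly 0.
* A categorical distribution with numeric category values is treated as a
  mixture of point masses by the continuous engine and reproduces the
  discrete formula to 1e-9, so the two formulas cannot drift apart.
* Tabulated inverted-V curves are interpolated with monotone (Fritsch-
  Carlson) cubic splines *per monotone segment*, joined at the nadir knot; a
  single spline across the extremum can undershoot the tabulated minimum
  and silently move the nadir.
* Rate metrics are never averaged: aggregation recomputes pooled rates from
  summed counts and populations, and refuses to proceed without
  populations. Percent metrics refuse summation outright.
* CSV output writes doubles with the shortest decimal representation that
  round-trips bit-for-bit, and the reader re-parses numerics through
  `strtod`, so write-then-read is the identity.

## Design choices where the design was open

* **Smoother instead of a spatial process.** The expected-PAF-by-SDI curve
  uses local linear regression (loess, span 0.5, direct surface) on a
  unit-SDI grid. A Gaussian-process formulation would need kernel and
  hyperparameter choices that have no published values to anchor them; the
  loess fit reproduces linear signals exactly and flat signals identically,
  which is what the smoothed expected curve is used for here.
* **Spearman p-values.** Exact permutation null (all `n!` permutations,
  cached per rank multiset) for `n ≤ 10`; the t approximation on `n − 2`
  degrees of freedom above that. Ties take average ranks.
* **SDI quintiles** are equal-count within the analysis cohort, with the
  k-th boundary at rank `round(nk/5)` and ties broken by location
  identifier — 204 locations split at ranks 41/82/122/163 — rather than
  against any published cutpoints.
* **Point estimate = mean of draws**, not the median; trend UIs are
  computed draw-wise. Both conventions are pinned for reproducibility.
* **Combined PAFs use the plain independence product.** Draw-level
  combination with mediation adjustments — which produces published
  combined figures such as 41.23% where the product of the printed per-risk
  PAFs gives about 43.5% — depends on unpublished mediation matrices and is
  intentionally out of scope; the gap is documented, not bridged.

## Problem sizes used by the shipped checks

The default synthetic world is 10 locations × 2 years × 8 age bands × 2
sexes × 3 risks (4 risk-outcome pairs) × 1000 draws — 2240 PAF strata
including the combined rows. The quadrature-versus-cohort oracle uses
10⁶-person Monte-Carlo cohorts; unit tests use smaller worlds (6 locations,
15-50 draws). These sizes were chosen so the full recovery check exercises
every code path at draw scale while remaining a desk-scale computation.

## Known limitations

* Exposure families are single parametric distributions per risk, not
  ensembles; the family is a required configuration choice, never guessed.
* TMRELs are point values; a counterfactual exposure *distribution*
  collapses to `RR(TMREL)` in the implemented formula.
* Published global and regional values (attributable DALY totals, combined
  PAFs, age-standardized rates against the unpublished standard population)
  require the full extract and draw-level internals and are not
  reproducible at this scale; the package asserts arithmetic identities on
  the published table and statistical recovery on synthetic data instead.
* Exposure and outcome are contemporaneous; lag between exposure and
  disease is not modelled.
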