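# craburden

Comparative risk assessment (CRA) of risk-attributable disease burden in R.

Burden-of-disease studies ask how much of a disease's toll — measured in
disability-adjusted life years (DALYs) — could be removed if the population's
exposure to a modifiable risk factor (tobacco, high body-mass index, high
fasting plasma glucose, low fruit intake, ...) were shifted to the
theoretical minimum-risk exposure level (TMREL). `craburden` implements that
framework end to end for epidemiologists and burden analysts who work with
GBD-style results extracts: exposure distributions fitted by the method of
moments, relative-risk curves, TMREL rules, population attributable
fractions (PAFs), attributable DALYs with draw-level uncertainty, direct
age-standardization, trend arithmetic, and sociodemographic-index (SDI)
analysis.

## The model

For a continuous exposure with density *P(x)* on support *[l, m]* and a
relative-risk curve *RR(x)*, the population attributable fraction is

```
        ∫ RR(x) P(x) dx  −  RR(TMREL)
PAF  =  ───────────────────────────────
              ∫ RR(x) P(x) dx
```

with the discrete analogue replacing integrals by sums over exposure
categories. The TMREL is 0 for harmful monotone-increasing risks, the curve
nadir for risks with a J/V-shaped dose-response, and the 85th exposure
percentile for protective risks such as fruit intake. Assuming independent
risk factors, per-risk PAFs combine multiplicatively:
`PAF = 1 − ∏ᵢ (1 − PAFᵢ)`. Attributable DALYs are `PAF × total DALYs` per
(cause, location, year, sex, age) stratum, computed draw-wise; 95%
uncertainty intervals are the 2.5th/97.5th percentiles across draws and
point estimates are draw means.

Because real GBD extracts are large and their draw-level internals
unpublished, the package ships a synthetic-world generator
(`generate_world()`) that emulates such an extract — multi-location,
age/sex-stratified exposures correlated with an SDI gradient, baseline DALYs,
draw noise — while recording ground-truth PAFs computed by an independent
quadrature, so the whole pipeline is testable for parameter recovery.

## Worked example

```r
library(craburden)

# a BMI-like stratum: mean 27, SD 4, lognormal; RR rises 2% per unit
bmi   <- fit_mom(mean = 27, sd = 4, family = "lognormal")
curve <- rr_curve("high_bmi", "colorectal_cancer", form = "log_linear",
                  beta = log(1.02), shape = "monotone_increasing", reference = 0)
paf_continuous(bmi, curve, tmrel = 0)
#> [1] 0.416
```

41.6% of this stratum's colorectal-cancer burden is attributable to the
exposure sitting above the counterfactual level. Running the full pipeline
on the default synthetic world (10 locations × 2 years × 8 age bands × 2
sexes, 3 risks, here with 200 draws):

```r
res <- run_pipeline(world_config(n_locations = 10, draws = 200, seed = 17))
res$trends[c("risk", "pct_change", "lower", "upper")]
#>   risk              pct_change lower upper
#> 1 _combined               51.3  48.5  54.4
#> 2 fruit_intake_like       57.5  52.3  62.5
#> 3 high_bmi_like           56.6  53.1  60.1
#> 4 tobacco_like            38.7  34.7  43.2

res$sdi_correlations
#>   risk                rho p_value     n
#> 1 high_bmi_like     0.370 0.296      10
#> 2 tobacco_like      0.830 0.00471    10
#> 3 fruit_intake_like 0.758 0.0149     10
#> 4 _combined         0.867 0.00217    10
```

The trend rows are percent changes in global attributable DALYs between the
first and last simulated year, with draw-level 95% intervals; the
correlation rows are Spearman tests of per-location PAF against SDI in the
latest year (exact permutation p-values at n ≤ 10). The same trend
arithmetic applied to published global values:

```r
percent_change(65478.5, 105037.38) |> round_half_up(2)
#> [1] 60.42
```

i.e. the 60.42% rise in all-risk attributable cancer DALYs from 1990 to
2019 in the bundled GBD 2019 table (`gbd2019_global_trends()`).

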