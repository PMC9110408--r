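# brecansurv

Survival indicators for hormone receptor-positive breast cancer cohorts
when the cause of death is unknown: all-cause Cox models combined with
population life tables to yield relative survival, conditional five-year
relative survival, excess mortality, and crude probabilities of death due
to the cancer versus other causes — for any patient profile (age, stage,
HER2 status, adherence to endocrine therapy), including adherent versus
non-adherent comparisons with bootstrap confidence intervals.

The intended users are cancer epidemiologists and biostatisticians
working with registry data where vital status is linked from mortality
registries but the specific cause of death is unavailable.

## Method in brief

The cohort's overall hazard λ_O(t | x) is estimated with a Cox
proportional-hazards model for all-cause mortality (age coded as
categories, a log-linear term, or a restricted cubic spline; adherence
constant or time-varying with a cut at 5 years — designs C1–C4, compared
by AIC). The population hazard λ_P(t) comes from a life table indexed by
attained age and calendar year. The excess hazard attributed to the
cancer is λ_X = λ_O − λ_P, and on a common monthly grid the package
derives

- OS(T) = exp(−∫ λ_O), ES(T) = exp(−∫ λ_P), RS(T) = OS(T)/ES(T),
- RS5(T) = RS(T+5)/RS(T) and EM(T) = (1 − RS5(T)) × 100,
- P_BC(T), P_OC(T) by apportioning the decrement of OS between λ_X and
  λ_P, with a matched discretisation so OS + P_BC + P_OC = 1 holds at
  every grid point.

A synthetic-cohort generator with known excess/population hazard
structure (and its analytic truth) makes the whole pipeline testable
without access to registry data. See the methods vignette
(`vignettes/brecansurv-methods.Rmd`) for the model, the numerical
scheme, and the generator's calibration.

## Worked example

```r
library(brecansurv)

cfg    <- sim_config(seed = 42)     # registry-scale synthetic cohort
cohort <- simulate_cohort(cfg)      # n = 1268, ~21% ten-year mortality
lt     <- sim_lifetable(cfg)        # the matching population life table

f3 <- fit_cox(cohort, "C3")         # spline age, constant adherence
f3
#> Cox all-cause mortality model (design C3)
#>   n = 1268, events = 321, AIC = 4191.53
#>      term covariate        hr        lo        hi
#>  age_rcs1       age 1.0762860 1.0402799 1.1135385
#>  age_rcs2       age 0.9987794 0.9696499 1.0287841
#>   stageII     stage 1.6753188 1.2804410 2.1919738
#>  stageIII     stage 3.2200444 2.4173270 4.2893188
#>   her2pos      her2 1.0615330 0.8264229 1.3635297
#>  adherent adherence 0.7216768 0.5454240 0.9548854
```

Indicator curves for a 60-year-old, stage III, HER2-negative patient not
adherent to endocrine therapy:

```r
ic <- predict_profile(f3, lt, list(age = 60, stage = "III",
                                   her2 = "neg", adherent = FALSE))
round(tail(ic[, c("time", "os", "rs", "rs5", "p_bc", "p_oc")], 1), 4)
#>     time     os     rs rs5   p_bc   p_oc
#> 121   10 0.5457 0.5786  NA 0.4114 0.0429
```

So for this profile the model predicts 54.6% overall survival at 10
years; a 41.1% probability of dying of the cancer and 4.3% of dying of
other causes by then; and a relative survival of 57.9% compared with the
general female population of the same age. At 5 years the conditional
five-year relative survival is RS5(5) = 0.738, i.e. an excess mortality
of 26.2% over the following five years compared with the general
population (RS5 is reported only up to horizon − 5, hence `NA` at 10).
The difference between the fitted stage III hazard ratio (3.22) and the
generator's excess-hazard truth (5.11) is the attenuation inherent in
fitting a proportional all-cause model to additive excess-plus-population
hazards; the vignette quantifies it.

Comparing adherence arms for the same profile:

```r
cmp <- compare_adherence(f3, lt, list(age = 60, stage = "III",
                                      her2 = "neg"))
round(cmp$difference, 4)            # non-adherent minus adherent P_BC(10)
#> [1] 0.1042
round(cmp$os_fold_change, 3)        # OS(10), adherent / non-adherent
#> [1] 1.184
```

`bootstrap_ci()` attaches percentile confidence intervals to any such
statistic by resampling patients and refitting;
`stage_comparison_table()` produces the per-stage adherent versus
non-adherent table pooled over the cohort's age distribution; and
`schoenfeld_diagnostic()` / `time_varying_ratio_test()` check the
proportionality of the adherence effect.

## Command line

A thin dispatcher wraps the same functions:

```sh
Rscript inst/cli/brecansurv.R simulate --out runs/sim --seed 7
Rscript inst/cli/brecansurv.R fit --config fit.yaml --out runs/fit
Rscript inst/cli/brecansurv.R predict --config profile.yaml --out runs/pred
Rscript inst/cli/brecansurv.R compare --config profile.yaml --out runs/cmp
```

Configs are YAML or JSON; artifacts are plain CSV/JSON with the seed and
a config hash stamped into `run.json`. Exit codes: 0 success, 1 runtime
failure, 2 usage/validation error.

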