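# promice

Simulation framework for choosing the level at which missing multi-item
patient-reported outcome measures (PROMs) are multiply imputed in
randomised controlled trials: at the **composite score**, the
**subscales**, or the individual **items**.

Trial statisticians and health-outcomes researchers face this choice
whenever follow-up questionnaires (a knee score, a generic health survey,
a utility instrument) come back partly or wholly unanswered. Item-level
imputation uses everything a partial response carries but multiplies the
number of conditional models; in small samples its ordinal models fail
through perfect prediction. Score-level imputation is robust but discards
the item information. `promice` turns that trade-off into a measurable
experiment.

## What the framework computes

A scenario fixes an instrument, a missing-data mechanism, a sample size
and a set of analysis methods, then repeats:

1. **Generate / subsample** a complete two-arm cohort. Outcomes come from
   a latent-health thresholding model: follow-up latent
   `theta_f = rho * theta_b + w'z + tau * arm + e`, items generated by
   cutting `a * theta + e_ij` at category thresholds, so items, subscales
   and composites are mutually coherent.
2. **Extract the truth** — complete-data per-arm means and the
   covariate-adjusted treatment effect (OLS of follow-up score on
   baseline score, arm, age, sex) — before anything is deleted.
3. **Ampute**: flag participants with probability
   `plogis(alpha + s_i)`, `s_i` a standardised weighted sum of arm, age,
   baseline score, height, ASA grade and centre size (`alpha` calibrated
   so the mean equals the target proportion p), then delete one
   nonresponse pattern per flagged participant — unit nonresponse or a
   specific item subset — drawn from a configured pattern mixture.
4. **Impute** by chained equations at the chosen level: Bayesian linear
   regression + predictive mean matching for continuous targets,
   proportional-odds models (compiled Newton–Raphson likelihood kernel)
   for ordinal items, with explicit non-convergence semantics
   (perfect prediction / zero cells / separation / overfit) and a
   configurable failure tolerance per imputation set. Complete-cases
   analysis runs alongside.
5. **Pool and score**: Rubin's rules (`T = W + (1 + 1/m) B`), then RMSE,
   MAE, bias, mean reported SE and convergence-failure proportion per
   method against the same-iteration truth.

Iterations whose imputation models fail to converge are replaced with
fresh sub-seeds up to an attempt cap; scenarios that cannot reach their
valid-iteration target are flagged insufficient, mirroring how such
feasibility limits are reported in practice.

## Worked example

```r
library(promice)

base <- generate_cohort(load_fixture("oks_base_case"), seed = 1)
#> <promice_cohort> 1030 participants, 37 columns
#>   baseline-follow-up composite correlation: oks=0.54

scn <- scenario(instrument_sim(oks_spec()),
                load_fixture("oks_observed_mixture"),
                p = 0.2, n = 200,
                methods = c("cca", "mi_score", "mi_item_ologit"),
                n_valid_target = 50, master_seed = 7,
                exploratory = TRUE, cycles = 3, base_case_n = 1030)
sim <- run_scenario(scn, base)
sim
#> <prom_sim> oks n=200 p=0.2: 50 valid / 50 attempted
#>   mi_score         chains 0/2500 failed (0.0%), 0 iteration failures
#>   mi_item_ologit   chains 0/500 failed (0.0%), 0 iteration failures

perf <- summary(sim)
perf[perf$estimand %in% c("overall", "treatment_effect"), ]
#>            method         estimand n_iter  rmse   mae   bias mean_se
#> 7             cca          overall     50 0.649 0.583 0.5725   0.832
#> 8  mi_item_ologit          overall     50 0.372 0.311 0.2366   0.807
#> 9        mi_score          overall     50 0.285 0.227 0.0066   0.839
#> 10            cca treatment_effect     50 0.640 0.506 0.0737   1.433
#> 11 mi_item_ologit treatment_effect     50 0.658 0.542 0.1851   1.417
#> 12       mi_score treatment_effect     50 0.716 0.586 0.1875   1.482
```

Reading the numbers: with 20% missing data at n = 200 under the observed
(mostly unit-nonresponse) pattern mixture, complete-cases analysis is
clearly biased for the **mean** composite score (missingness depends on
covariates, so the surviving cases are unrepresentative: bias 0.57 points
on the 0–48 scale), while score-level imputation is nearly unbiased
(0.007) and most accurate (RMSE 0.285); item-level ordinal imputation
sits between them. For the covariate-adjusted **treatment effect** all
three methods perform similarly — the MAR drivers are in the analysis
model, which is exactly the regime where complete-cases analysis remains
valid for the effect even though it fails for the means.

Single pieces of the pipeline are exported on their own:
`score_composite()`, `score_subscales()`, `score_eq5d()`,
`score_normed()`, `classify_pattern()`, `ampute()`,
`missingness_propensity()`, `fit_ologit()` / `impute_ologit()`,
`fit_bayes_linreg()` / `impute_pmm()`, `run_chain()`,
`generate_imputations()`, `fit_analysis_model()`, `rubin_pool()`,
`run_scenario()`, `compute_performance()`, `report()` (with a base-R
`plot()` method for RMSE-versus-p grids).

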