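---
title: "Choosing the level of multiple imputation for multi-item patient-reported outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing the level of multiple imputation for multi-item patient-reported outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promice)
```

## The question the framework answers

Multi-item patient-reported outcome measures (PROMs) are summarised into
composite scores and, sometimes, subscales. When follow-up questionnaires
go missing in a randomised trial — wholly (unit nonresponse) or partially
(item nonresponse) — the analyst who reaches for multiple imputation by
chained equations (MICE) faces a modelling choice with no obvious answer:
impute the **composite score** directly, impute the **subscales**, or
impute every **item** and re-score. Item-level imputation uses all the
information the partial responses carry, but multiplies the number of
conditional models and parameters; in small samples its ordinal models
routinely fail through perfect prediction. `promice` implements the whole
comparison as a simulation framework: generate a realistic trial cohort,
impose missing-at-random (MAR) data with a configured mixture of
nonresponse patterns, impute at each level, estimate the trial quantities,
and score every method against the same-iteration complete-data truth.

## The simulated trial

`generate_cohort()` draws a two-arm trial with the covariates typical of
an elderly surgical population: age (normal, mean 70, sd 8), sex, height
(sex-specific normals), ASA physical-status grade (three levels, mostly
1–2) and the size of the recruiting centre (three categories: fewer than
30, 30–100, more than 100 participants). Outcomes are produced by a
latent-health thresholding model (graded-response style): participant $i$
has a baseline latent $\theta^b_i$ loading on standardised covariates, and
a follow-up latent

$$\theta^f_i = \rho\,\theta^b_i + \mathbf{w}^\top \mathbf{z}_i +
\tau\,\mathrm{arm}_i + \varepsilon_i,$$

with the variance components chosen so each latent has unit variance. Item
$j$ of an instrument is generated by thresholding
$a\,\theta_i + e_{ij}$ at cutpoints set from configured marginal category
probabilities, so items are mutually correlated through the latent and the
stored composites always equal a re-scoring of the items.

Three instrument shapes are shipped as fixtures:

* `oks_spec()` — 12 five-level items scored 0–4, composite 0–48, up to two
  missing items replaced by the mean of the observed item scores, and a
  configurable pain (items 1–7) / function (items 8–12) subscale split.
  The split is a documented default, not a validated mapping, because the
  validated partition is not public in item-index form.
* `sf12_spec()` — 12 mixed-level items scored into physical and mental
  components by a configurable two-factor weight matrix standardised
  against a reference sample so that the reference population scores mean
  50, sd 10. Proprietary scoring coefficients are deliberately not
  reproduced; the analysis only requires the mean-50/sd-10 norm structure.
* `eq5d_spec()` — five three-level dimensions valued by an additive
  tariff (constant decrement 0.081 for any departure from full health,
  per-dimension level decrements, 0.269 extra if any dimension is at its
  worst level). The full-health state is anchored at utility 1 exactly,
  and the constructor asserts it.

Key generator defaults, and why:

* **Treatment effect** `tau = 0`: the emulated trial setting has a
  near-null effect; recovery tests use a small positive `tau` and map it
  to the composite scale with `implied_composite_effect()`, which
  integrates the thresholding model over the latent distribution (a
  closed-form oracle independent of the generator's sampling path).
* **Autoregression** `rho = 0.55`: after attenuation through
  categorisation this lands the baseline–follow-up composite correlation
  in the low-to-moderate band `[0.3, 0.6]` typical of trial datasets; the
  generated cohort stores its achieved correlation and warns when a large
  cohort falls outside the band.
* **Item marginals**: follow-up distributions are shifted toward good
  outcomes with a deliberately rare worst category (4% for five-level
  items, 7% for the utility dimensions). Sparse extreme categories are the
  realistic feature that drives ordinal-model failure in small samples,
  which is central to the phenomenon under study.

What the generator does **not** emulate: deaths and withdrawals,
multi-timepoint follow-up, centre-level clustering, and real KAT-trial
marginals (the source data are not deposited, so item-level distributions
are stated defaults, not calibrated estimates). Passing tests therefore
demonstrate internal validity of the machinery and directional agreement
with the published comparison, not numerical reproduction of the original
trial's results.

## The missingness mechanism

`ampute()` flags each participant independently with propensity
$\mathrm{logit}^{-1}(\alpha + s_i)$, where $s_i$ is the standardised
weighted sum of treatment arm, age, baseline composite, height, ASA grade
and centre size (integer coding for the categorical predictors), and
$\alpha$ is calibrated by bisection until the mean propensity equals the
target proportion to within $10^{-6}$. Each flagged participant then draws
one missingness pattern — unit nonresponse or a specific item subset —
from a configured `pattern_mixture()`. The shipped mixtures follow the
observed-pattern tables of the motivating study (unit-nonresponse shares
of 73.1%, 56.1% and 87.9% for the knee score, health survey and utility
instrument respectively); because the printed columns do not sum exactly
to 100%, fixtures renormalise to a simplex and retain the raw percentages.
Baseline data are never deleted, and sex is deliberately absent from the
missingness score while present in the analysis model, mirroring the
study's design. Missing-not-at-random mechanisms are out of scope.

## The imputation engine

All levels run through the same chained-equations loop (`run_chain()`):
random initial fill from observed values, then a fixed visiting order of
conditional models for a configurable number of burn-in sweeps (default
10), re-imputing the originally missing entries each sweep. A chain with a
single incomplete variable needs only one sweep and is run that way, which
also makes the single-variable chain exactly equal to one direct
imputation — a tested oracle equivalence.

* **Continuous targets** (composites, subscales, items in numeric mode)
  use Bayesian linear regression plus predictive mean matching: one draw
  from the standard noninformative posterior predicts the missing rows,
  the posterior-mean fit predicts the observed rows, and each missing row
  receives the observed value of one of `k = 5` nearest-prediction donors
  (type-1 matching). The donor count is configurable because the
  originating software's setting is not documented; 5 is the conventional
  default. PMM guarantees imputed values stay inside the observed support.
* **Ordinal targets** use a proportional-odds model fitted by
  Newton–Raphson with analytic gradient and Hessian (the likelihood
  kernel is compiled code, since item-level simulation needs on the order
  of $10^5$ fits). Parameter uncertainty for the draws comes from the
  normal approximation at the MLE in an unconstrained cutpoint
  parametrisation, so drawn cutpoints are always increasing. Failure is a
  first-class outcome with structured reasons: a category with zero
  observed cases in an arm stratum, fewer than two observed categories,
  non-finite likelihood improvement, or any coefficient above 10 in
  absolute value on the unit-variance predictor scale (separation in all
  but name) report `perfect_prediction`; a non-invertible observed
  information reports `singular_information`; too few rows report
  `overfit`.

`generate_imputations()` attempts chains one at a time with counter-derived
sub-seeds until `m` succeed, aborting the whole set once failures exceed
`failure_tolerance × attempted` (default tolerance 0.5). Imputation runs
separately by treatment arm where feasible; item-level models of
instruments with more than five items instead run pooled with arm as a
covariate — the workable compromise for models that rarely converge by
arm — and a failed by-arm set can fall back to that pooled form, with the
by-arm failures kept in the convergence accounting.

Default imputation counts follow the study conventions: `m = 50` at score
and subscale level; at item level `m = 50` for the full base-case sample,
`m = round(100p)` for smaller samples, and `m = 10` for exploratory
scenarios. Default predictor sets contain the baseline composite (replaced
by the baseline subscales at subscale/item level, since the composite is
their exact sum and including both is collinear), age, sex, height, ASA
grade, centre size, the other targets of the level, and arm when pooled.

## Estimation and performance

The trial estimands are the per-arm and overall unadjusted means and the
covariate-adjusted treatment effect from ordinary least squares of the
follow-up score on baseline score, arm, age and sex. Complete-cases
analysis is the same model on the rows whose outcome survives the
partial-response scoring rules. Multiply-imputed estimates are pooled by
Rubin's rules ($T = W + (1 + 1/m)B$) with the large-sample degrees of
freedom by default and the Barnard–Rubin adjustment by flag — the
originating software's era makes either defensible.

`run_scenario()` iterates subsample → truth → ampute → score → analyse
with counter-based sub-seeds (a failed iteration never perturbs later
ones), until the valid-iteration target is met or the attempt cap
(11 × target by default) is reached; under-target scenarios are flagged
insufficient and excluded from comparisons. Truth is the per-iteration
complete-data estimate, not the generative parameter; the generative
composite-scale effect is available separately for bias diagnostics. The
subsample is redrawn every iteration by default (a fixed-subsample mode
exists), since the source description is ambiguous on this point.
`compute_performance()` reports RMSE, MAE, bias, mean reported SE,
empirical sd and the chain-level convergence-failure proportion; the
identity $\mathrm{RMSE}^2 = \mathrm{bias}^2 + \widehat{\mathrm{Var}}$
holds to numerical precision and is tested.

## A worked example

```{r example, eval = FALSE}
library(promice)

base <- generate_cohort(load_fixture("oks_base_case"), seed = 1)
scn <- scenario(instrument_sim(oks_spec()),
                load_fixture("oks_observed_mixture"),
                p = 0.2, n = 200,
                methods = c("cca", "mi_score", "mi_item_ologit"),
                n_valid_target = 100, master_seed = 7,
                exploratory = TRUE, cycles = 3, base_case_n = 1030)
sim <- run_scenario(scn, base)
summary(sim)
```

## Numerical and design choices

* **Burn-in cycles** default to 10 (conventional for chained equations;
  the source is silent); the reduced-scale replication runs in the test
  suite use `m = 10` with 60–200 valid iterations per scenario. Burn-in
  there follows a bias diagnostic: under predominantly unit nonresponse
  the chained targets feed each other and mix slowly away from the
  marginal initial fill, so 3 sweeps leave a visible upward bias in the
  imputed composite means (about +0.13 points), 10 sweeps suffice for the
  proportional-odds chains, and the PMM-based chains (items as
  continuous, subscales) need about 25 sweeps before their bias vanishes
  (+0.03 at 10 sweeps, < 1e-4 at 25). The convergence-failure accounting
  uses 3 cycles, since failure detection happens before any fitting and
  is burn-in independent —
  problem sizes chosen so the full suite runs comfortably on one core
  while leaving the qualitative comparisons identifiable.
* **Visit order** is fixed ascending item index, for determinism.
* **Seeds**: every public entry point takes an explicit seed; internal
  sub-seeds derive from `(master, counter)` so that retries are
  reproducible and independent.
* **Degenerate inputs**: empty expected item categories are a
  configuration error at construction time; rank-deficient designs,
  starved strata and separations surface as structured non-convergence,
  never as silent estimates.
* **Score-level handling of partially scoreable composites**: participants
  whose composite survives the missing-item tolerance are scored, not
  imputed; only undefined composites enter the imputation model, mirroring
  scoring-manual precedence.

## Known limitations

Item-level imputation treats categorical predictors by integer coding;
centre effects are not modelled as random effects; the norm-based scoring
model is a structural stand-in, so its component scores are comparable
within a simulation but not to published population norms; and the
convergence-failure rates observed here depend on the configured item
marginals — sparser extreme categories produce more failure, denser ones
less — so they replicate the direction, not the magnitudes, of the
motivating study's feasibility findings.
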