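---
title: "Auditing deficit-accumulation frailty indices: methods and design"
author: "frailtyaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing deficit-accumulation frailty indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtyaudit)
```

## What this package audits

Composite frailty indices summarize many health deficits into one score.
Three constructions dominate the literature, and `frailtyaudit`
implements all three on a common cohort table:

* **Functional Domains** — four [0,1] domain variables (physical,
  nutritive/weight-loss, cognitive, sensory functioning), each an
  "any-problem" indicator built by right-censoring a sum of binary
  deficits at 1. Index = sum of the four domains, range [0,4]; frail iff
  index ≥ 2; intended for ages 65+.
* **Burden (deficit accumulation)** — 24 equal-weight items: binary
  deficits coded 0/1, ordinal symptom scales rescaled to [0,1] by
  `(rank − 1)/(K − 1)` (so five categories map to 0, 0.25, 0.5, 0.75,
  1), plus one cognition domain combining two cognition scores. Index =
  item sum divided by 24, range [0,1]; frail iff ≥ 0.2; ages 70+.
* **Biologic Syndrome** — five domains: weight loss (shared with the
  Functional Domains nutritive domain), exhaustion, and three
  stratified-quantile criteria — slowness (slowest 20% of 15-foot walk
  time, converted from the measured 8-foot time by the factor 15/8,
  within sex × height strata), weakness (weakest 20% grip strength
  within sex × BMI-quartile strata), and low energy expenditure (lowest
  activity quintile within sex). Index = domain sum, range [0,5]; frail
  iff ≥ 3; ages 65+.

Every one of these construction steps — rescaling ordinal ranks as if
they were interval data, censoring sums, thresholding continuous
measures at stratum quantiles, and finally dichotomizing the index —
injects information that is *not* a linear function of the underlying
input variables. The audit quantifies exactly that.

### Bias variables

For each domain $d$ with input design columns $X_d$ (binary and ordinal
inputs entering as their scaled values), the **bias variable** is the
ordinary-least-squares residual

$$b_d = d - X_d\hat\beta_d,$$

with intercept, so $b_d$ has mean zero and is orthogonal to $X_d$. The
decomposition $d = \hat d + b_d$ holds at machine precision, which gives
the package its central identity: regressing any constructed index on
the union of its own input columns and its domains' bias variables
yields $R^2 = 1$ (checked to $10^{-8}$), while $1 - R^2_{\text{inputs}}$
is the share of index variance created purely by data manipulation.
Dichotomization bias is reported separately as `status − index`: an
index of 0.9 at cutoff 0.2 needs +0.1 of bias to become the status 1,
an index of 0.1 needs −0.1. Nine domain-level bias variables exist by
default (four Functional-Domains + five Biologic-Syndrome domains with
weight loss shared, plus the Burden cognition domain); the
dichotomization bias is not one of the nine.

A subtlety worth recording: for a censored sum such as the sensory
domain ($\min(h + e, 1)$), the OLS residual is constant within each
$(h, e)$ cell and nonzero in *all four* cells — not only for
participants with both problems. Only the construction arithmetic
itself (domain minus raw sum) is confined to the both-problems cell,
where it equals −1. Tests assert both facts separately.

### Interpretation and simplification

Indices (continuous) and statuses (dichotomous) are approximated with
forward-stepwise regression: at each step every remaining candidate is
refit and the one minimizing AIC ($2k - 2\log L$, `stats::AIC`
convention) is accepted iff it strictly lowers the AIC; ties are broken
by candidate name order, so paths are order-invariant and
deterministic. For statuses, fit is summarized by McFadden's
pseudo-$R^2$ with a parameter-count-adjusted variant
($1 - (\log L - k)/\log L_0$) and in-sample AUC; which pseudo-$R^2$ the
original analyses used is not documented anywhere we know of, so the
choice is declared rather than guessed. `variables_to_reach()` reports
the smallest step reaching a stated fraction (default 90%) of the
path's maximum $R^2$ — the "how much can this index be simplified"
number. Candidates whose logistic fit separates (or fails to converge)
are skipped and logged, never fatal.

### Survival analysis

Mortality prediction uses discrete-time survival analysis: the cohort
is expanded to one row per person-year, and the yearly death indicator
is modelled by logistic regression on period dummies (one baseline
log-odds per year — no smoothing), the predictor set under comparison,
and the adjustment covariates (sex, race/ethnicity, education,
per-capita income and wealth). With saturated period dummies only, the
predicted hazards reproduce the Kaplan-Meier estimator exactly; this is
tested at $10^{-8}$. Cox models are deliberately out of scope.
Representations of the same model — continuous index, status, domains,
bias variables, raw inputs — are compared on AUC of the fitted
per-row event probabilities (DeLong 95% CI), AIC and residual deviance.
Because the index is a constrained linear combination of its columns,
the inputs representation can never have worse deviance than the
equal-weight index: an exact nesting the tests assert on every run.

Death in year $t$ is credited to period $t$ (ties between interview and
death dates within a year are not modelled). Rows with missing
covariates are dropped with a logged count.

### Alternative-index mining

`enumerate_k_subsets()` streams all $\binom{n}{k}$ equal-weight
candidate definitions (an index needs at least two variables);
`mine_indices()` fits each candidate's covariate-adjusted hazard model
and records the Wald p-value of the index term, the AIC and the
residual deviance. Over the default 72-variable menu with $k = 4$ the
universe is exactly 1,028,790 definitions; the shipped configuration
mines desk-scale pools (≤ 20 variables) and the full run is available
by simply passing `fa_pool()`. The per-candidate fits reuse one
prebuilt design matrix for speed; a test proves the fast path equals
independent one-at-a-time `glm` refits. Candidates touching a variable
unmeasured in the analysis sample are skipped with a logged count.
No multiple-testing correction is applied to mined p-values — that is
a property of the audited practice, noted, not fixed. Note that
candidates sharing variables have strongly correlated p-values: on a
null cohort the *fraction* significant at 0.05 is unbiased but has a
sampling sd near 0.09 for a 12-variable pool, so calibration checks
average over replicate cohorts.

## The synthetic cohort generator

The real data behind these indices (a national aging panel) is
registration-restricted, so the package ships a generator that emulates
the statistical structure the audit assumes, and nothing more:

* One latent frailty propensity per participant,
  $Z = \mathrm{std}(\mathrm{std}(\text{age}) + \varepsilon)$,
  $\varepsilon \sim N(0,1)$. A single factor is the simplest structure
  that makes deficits mutually correlated, age-graded and prognostic —
  all that the downstream stages assume.
* Binary deficits: $\Pr(d_j = 1) = \mathrm{logit}^{-1}(a_j + L \cdot Z)$
  with per-deficit baselines $a_j$ set to community-typical prevalences
  (2%–45%) and one global loading `frailty_loading` $L$ (default 1).
  Ordinal scales come from a thresholded latent $0.8 L Z + N(0,1)$.
* Performance measures with the dependencies the stratified criteria
  need: walk time log-normal, increasing in $Z$, slower for women and
  shorter participants; grip strength normal, decreasing in $Z$, higher
  for men and heavier participants; activity log-normal decreasing in
  $Z$; height sex-specific; weight from a BMI draw decreasing mildly
  in $Z$.
* Survey weights i.i.d. gamma with mean 1 (variance
  `weight_dispersion`, default 0.5) — positive and right-skewed like
  design weights; the exact family is irrelevant to correctness and no
  claim about real weight construction is made.
* Mortality: yearly discrete-time logistic hazard, default intercepts
  rising from 3.5% to 8% per year over at most 13 years of follow-up,
  default log-odds 0.8 on $Z$ — chosen so that roughly half the cohort
  dies during follow-up, in line with published survival tables for
  such panels.
* Missingness: MCAR or MAR-age (probability increasing with age);
  demographics and the survival outcome are never masked.

Defaults put weighted frailty prevalence among the age-eligible at
roughly 36% (Functional Domains), 55% (Burden) and 18% (Biologic
Syndrome), with nonzero prevalence below the age cutoffs — the
qualitative pattern the audit methodology highlights. Prevalence rises
monotonically with `frailty_loading` (a tested property), so other
regimes are one parameter away.

What the generator does **not** emulate: real marginal distributions or
variable wording, multi-wave interview structure (a single baseline
plus survival suffices), informative censoring, and design-based
clustering behind the survey weights. Passing tests therefore show the
*machinery* is correct under the stated generative assumptions, not
that any particular substantive estimate transfers to real data.

Seeds: `generate_cohort(spec)` uses `spec$seed` for the baseline table,
`spec$seed + 1` for survival and `spec$seed + 2` for missingness, and
restores the caller's RNG state. When adding user columns to a
generated cohort in simulations, seed them well away from this stream.

## Missing values

Two construction modes are supported. The replication default imputes
first (`impute_chained()`) and then constructs. The alternative,
missing-as-category, scores a missing item as the reference
(no-deficit) category and never flags a missing continuous measure; the
original descriptions say missing values formed their own category but
not how that category scores, so this convention is declared here.

`impute_chained()` is iterative conditional imputation producing a
single completed dataset (the audited analyses used one): random-draw
initialization, then per variable a regression on all other imputation
variables plus demographics — Bernoulli draws from a logistic fit for
binary variables, a rounded and range-clamped linear-latent draw for
ordinal ranks, and predictive mean matching (5 donors) for continuous
measures, which keeps imputations on the observed support (walk times
stay positive). Ten cycles by default; deterministic given its seed.

## Numerical choices

* **Quantile tie rule.** The stratum threshold is the smallest value at
  which the (optionally weighted) cumulative fraction reaches $q$; all
  ties at the threshold are flagged. Deterministic, and it reproduces
  the over-coverage phenomenon: unweighted thresholds applied to a
  skew-weighted sample can flag far more (or less) than $q$ of the
  weighted population. Unweighted thresholds are the replication
  default; weighted mode covers $q$ of total weight to within one
  observation's weight.
* **Rank deficiency.** All bias regressions go through `lm`'s pivoting
  (pseudo-inverse behaviour): collinear inputs give valid least-squares
  residuals, never an error.
* **Stopping.** Stepwise stops when no candidate strictly lowers AIC,
  or at a numerically perfect linear fit ($R^2 \ge 1 - 10^{-12}$),
  where AIC comparisons are rounding noise.
* **Walk-time units.** Stored as seconds for 8 feet; the 15/8
  conversion is applied exactly once, before thresholding.
* **In-sample AUC optimism.** Representation AUCs are computed on
  fitted probabilities; fitting $k$ coefficients to pure noise inflates
  the in-sample AUC slightly (~0.52–0.53 for 4–9 predictors at the
  problem sizes used here), so on null data only single-coefficient
  representations are expected to have DeLong CIs covering 0.5.

## Problem sizes used by the test-suite

Tests construct all fixtures in code. The heavier checks use: n =
20,000 participants for decomposition identity, independence and
prevalence-monotonicity checks; 40 replicates of 2,500 participants ×
≤ 8 years (20,000 person-years) for hazard-coefficient recovery; 50
replicates of 1,200 participants for the continuous-vs-status
comparison; 10 replicate null cohorts of 1,500 for miner calibration;
pools of 8–12 variables (70–495 fits) wherever mining is
oracle-checked. The full 72-choose-4 enumeration is exercised for its
count; million-fit mining runs are supported but not part of the
default suite.

## Known limitations

* Bias is defined by linear fits; tree- or spline-based decompositions
  are out of scope, as are causal readings of "bias".
* The mined p-values are uncorrected for multiplicity by design (the
  practice being audited applies none).
* The single-latent-factor generator cannot produce domain-specific
  correlation structure; auditing conclusions that depend on
  multi-factor deficit structure need a richer simulator.
* Person-period models assume yearly intervals and baseline-constant
  covariates; time-varying predictors beyond the period dummies are not
  supported.
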