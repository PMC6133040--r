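---
title: "Regression standardization and causal effect measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression standardization and causal effect measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdcausal)
library(survival)
```

## The estimand and the estimator

Let $X$ be an exposure, $Y$ a binary outcome, and $Y_x$ the potential outcome
under exposure level $x$.  The counterfactual probability
$p(Y_x = 1)$ — the outcome probability if the whole population were set to
$X = x$ — identifies a wide family of causal effect measures.  If a measured
covariate set $Z$ is sufficient to control confounding,

$$p(Y_x = 1) = E\{p(Y = 1 \mid X = x, Z)\},$$

with the expectation over the population distribution of $Z$.  Regression
standardization (the parametric g-formula) estimates the right-hand side by
(i) fitting a regression model for $p(Y \mid X, Z)$, (ii) predicting at
$X = x$ for every observed $Z_i$, and (iii) averaging:

$$\hat p(Y_x = 1) = \frac{1}{n} \sum_{i=1}^n \hat p(Y = 1 \mid X = x, Z_i).$$

`std_glm()` implements this for logistic models fitted by `fit_glm()`.  A
distinguished `FACTUAL` level keeps each subject's observed exposure, so the
same machinery also estimates the factual probability $p(Y = 1)$; for models
containing an intercept, that estimate equals the sample prevalence exactly,
because the intercept's score equation forces the fitted values to average to
the outcome mean.  `FACTUAL` is a sentinel object rather than a missing-value
code, so genuinely missing exposures can never be mistaken for a request for
factual predictions.

For time-to-event outcomes, $Y(t)$ indicates an event by time $t$ and the same
three steps apply at each requested $t$, with the conditional event
probability taken from a Cox model:
$\hat p\{Y(t) = 1 \mid X = x, Z_i\} = 1 - \exp\{-\hat\Lambda_0(t)
e^{z_i(x)'\hat\beta}\}$, where $\hat\Lambda_0$ is the Breslow baseline
cumulative hazard.  `std_coxph()` returns standardized **survival**
probabilities $1 - \hat p\{Y_x(t) = 1\}$ (times in rows, exposure levels in
columns), one variance matrix per time.

## Effect measures as contrasts

Any effect measure expressible as a smooth contrast $g(\mathbf p)$ of
standardized probabilities is supported through `estimate_effect()`:

* attributable fraction $\mathrm{AF} = 1 - p(Y_0{=}1) / p(Y{=}1)$, the
  proportion of events prevented by eliminating the exposure;
* number needed to treat
  $\mathrm{NNT} = 1 / \{p(Y{=}1 \mid X{=}0) - p(Y_1{=}1 \mid X{=}0)\}$, where
  the second term is the counterfactual risk under treatment *among the
  factually untreated* — estimated by restricting the standardization average
  to that subset (`subset =` argument);
* relative excess risk due to interaction
  $\mathrm{RERI} = \{p(Y_{11}{=}1) - p(Y_{10}{=}1) - p(Y_{01}{=}1) +
  p(Y_{00}{=}1)\} / p(Y_{00}{=}1)$ for a joint four-level recode of two binary
  exposures (`recode_joint()`);
* risk difference and risk ratio.

Variances follow the delta method,
$\widehat{\mathrm{var}}\{g(\hat{\mathbf p})\} =
\nabla g' \, \widehat{\mathrm{var}}(\hat{\mathbf p}) \, \nabla g$, with
analytic gradients (checked against central differences in the test suite).
Wald intervals use the exact normal quantile (`qnorm(0.975)` = 1.959964, not
a hard-coded 1.96).  For positive measures such as the NNT the default
interval is computed on the log scale and back-transformed,
$\exp[\log g \pm z\,\mathrm{se}/g]$, which keeps the limits positive and
typically improves coverage; AF, RD, RR and RERI default to the identity
scale.  Both defaults can be overridden.

Two orientation rules are deliberate:

* Contrasts always consume **event** probabilities.  Survival results store
  survival probabilities, and the conversion $p = 1 - \mathrm{surv}$ happens
  in exactly one place (`estimate_effect()`), so a curve can never be flipped
  twice.
* An NNT at a time point where the estimated risk difference is non-positive
  is reported as an infinite or negative estimate with a structured `warning`
  field, not an error, so that time-indexed curves with crossing survival do
  not abort.

## Variance estimation: stacked estimating equations

The joint variance of $\hat{\mathbf p}$ across exposure levels is a sandwich
estimator for the stacked system consisting of the model's score equations
and, for each level $x$, the standardization equation
$\sum_{i \in S} \{p(Y{=}1 \mid X{=}x, Z_i; \beta) - \theta_x\} = 0$ over the
standardization set $S$.  In influence-function form, each observation
contributes

$$\mathrm{IC}_i(\theta_x) = \frac{\mathbb 1(i \in S)\{p_i(x) - \theta_x\}}{|S|}
  + g_x' \, I^{-1} U_i,$$

with $U_i$ the score contribution, $I$ the information and $g_x$ the averaged
gradient of the prediction in $\beta$.  When a cluster identifier is supplied
(e.g. births nested in mothers), contributions are summed within cluster
before the outer product — the usual cluster-robust correction, which changes
variances but never point estimates.  Two exact closed forms anchor this
machinery in the tests: for an intercept-only model the factual variance is
$\hat p(1-\hat p)/n$, and singleton clusters reproduce the unclustered
variance bit for bit.

For the Cox engine the estimator depends on $(\hat\beta, \hat\Lambda_0)$, so
the influence function has three parts: the direct averaging term, a
$\hat\beta$ term through the score residuals and inverse information, and a
Breslow term using the standard counting-process influence of the baseline
hazard estimator (a martingale-increment sum minus $H(t)' I^{-1} U_i$, with
$H(t) = \int_0^t \bar z \, d\Lambda_0$).  The $\beta$-gradient of the
standardization equation is analytic and verified against central differences
(agreement demanded to 1e-4); the whole Cox variance is validated against a
nonparametric bootstrap rather than a formula-level identity.  Per-time
variance matrices only are computed; cross-time covariances (and hence
simultaneous bands) are out of scope — intervals on curves are pointwise.

`bootstrap_se()` provides the independent resampling route (resampling whole
clusters when a cluster column is given).  It serves both as a fallback
variance engine and as the oracle in the acceptance tests, where delta-method
standard errors for standardized probabilities, AF and NNT must agree with
2000-replicate (cluster-)bootstrap standard errors to 10%.

## Modelling choices

* **Fitting backends.**  Logistic models are fitted by iteratively
  reweighted least squares via `stats::glm` (convergence: relative change
  below 1e-10 within 100 iterations; non-convergence, rank deficiency and
  detected separation are errors, never warnings), but score contributions
  and the information matrix are always recomputed from the final
  coefficients so the variance machinery is independent of backend
  internals.  Cox models are fitted by `survival::coxph`.
* **Ties.**  The partial likelihood defaults to the Efron tie correction
  (`ties = "breslow"` is available and is used in the hand-checkable
  fixtures); the baseline hazard is always the Breslow estimator.  The
  cumulative hazard is right-continuous: a prediction at an event time
  includes that event's increment, and requests beyond the last event time
  warn and use the flat tail.
* **Counterfactual design construction.**  The model records its terms,
  factor levels and contrasts at fit time; setting $X = x$ rebuilds the model
  frame from raw columns, so every exposure-dependent design column — main
  effects, interactions, transforms such as `I(exp(-0.12 * nodes))` — is
  recomputed consistently.  Unseen factor levels are errors.  Categorical
  codings are reference (treatment) codings with the recorded first level as
  reference, so runs are reproducible.
* **Missing data.**  Complete-case analysis on the referenced columns, with
  the dropped-row count logged.
* **Subsets.**  Subset standardization (needed for the NNT) accepts a logical
  vector, a character comparison such as `"nosmoke == 0"`, or a one-sided
  formula.  Within a subset, `FACTUAL` estimates the factual probability *in
  that subset* — for a binary main-effect exposure this equals the observed
  subset prevalence (a score-equation identity), distinct from the
  whole-population factual probability.

## What the synthetic generators emulate

`generate_binary()` emulates a perinatal-style clustered design: 188 mothers
with one to five births each (cluster-size mean about 2.6, so roughly 490
births), a harmful binary exposure with prevalence about 0.4 assigned
dependently on the confounders, a three-level categorical and a continuous
confounder, outcome prevalence about 0.3, and exchangeable within-cluster
dependence induced by a latent normal random intercept (sd 0.75) in the
outcome model.  The real phenomenon being mimicked — repeated births to the
same woman — is cluster dependence of unknown form; any exchangeable
dependence suffices to exercise the sandwich correction, so a random
intercept is the simplest faithful choice.

`generate_survival()` emulates a breast-cancer-registry shape: 2982 patients,
a harmful exposure standing for withheld adjuvant treatment (marginal
prevalence about 0.4, assigned dependently on age, menopausal status and
tumour size), a Weibull(shape 1.2, scale 120 months) baseline hazard,
proportional hazards with exposure log hazard ratio 0.5, a Poisson(2.7)
nodes-like count entering through the deterministic transform
$\exp(-0.12 \cdot \mathrm{nodes})$, and uniform censoring on (36, 240) months
giving an event fraction near one half.

Both generators are bit-deterministic given their seed.  `true_estimands()`
computes the generative-law values of every estimand by Monte-Carlo
integration over the covariate law (its own seed, at least 1e5 draws,
default 1e6), reporting a Monte-Carlo standard error with every value so
simulation tolerances can be stated in MC-SE units rather than as ad-hoc
constants.

What the generators do *not* emulate — and therefore what passing tests do
not establish about real data: informative or dependent censoring,
non-proportional hazards, model misspecification (the analysis models are
correctly specified up to the random intercept), measurement error, and
unmeasured confounding.  In particular, marginalizing the random-intercept
outcome model over clusters induces a mild attenuation relative to the
conditional coefficients; the standardization estimand targeted by the
fitted (marginal) model is what `true_estimands()` reports, so estimator and
truth remain aligned.

## Problem sizes used in validation

The test suite validates at sizes chosen to balance Monte-Carlo resolution
against a comfortable laptop run: oracle-equality and closed-form checks on
fixtures of 3-600 rows; bootstrap agreement with 2000 replicates on about
600 clustered and 2000 independent-ish observations; estimand recovery at
about 5000 observations against 1e6-draw generative truth; and interval
coverage over 1000 replicates of about 1000 observations each, with the
93-97% acceptance band implied by binomial noise around a nominal 95%.

## Known limitations

Links other than the logit are not wired in (the inverse link lives in one
place, so probit or log links are addable); no time-varying covariates,
stratified baselines, left truncation or competing risks in the Cox engine;
no standardization over external covariate distributions, inverse-probability
weighting or doubly-robust estimation; no shared-frailty models.  The
delta-method NNT interval inherits the instability of a reciprocal near a
null risk difference — at small samples or weak effects, prefer the log
interval (the default) and read the structured warnings.
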