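---
title: "How unstable are shrinkage and tuning estimates in clinical prediction models?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How unstable are shrinkage and tuning estimates in clinical prediction models?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrinkstab)
library(dplyr)
```

## The problem

Clinical prediction models fitted by ordinary maximum likelihood (ML) are
overfitted to their development data: predicted risks are too extreme when the
model is applied to new individuals, and increasingly so as the sample size
falls, the candidate predictor count rises, or (for binary outcomes) the event
count drops. Two families of remedies are in routine use:

* **Uniform (global) shrinkage**: fit by ML, then multiply every predictor
  effect by a single factor $S \in (0, 1]$ and re-estimate the intercept
  $\alpha^*$ so that calibration-in-the-large is preserved,

  $$\operatorname{logit}(\hat p_i) = \alpha^* + S\,(\hat\beta_1 x_{1i} + \hat\beta_2 x_{2i} + \dots).$$

* **Penalized estimation**: maximize the log-likelihood minus a penalty
  $\lambda\,\mathrm{pen}(\beta)$ during fitting — ridge
  ($\tfrac12\sum\beta_j^2$), lasso ($\sum|\beta_j|$), or their elastic-net
  mixture.

Both $S$ and $\lambda$ are themselves **estimated from the development data**,
and this package exists to quantify how uncertain those estimates are and what
that uncertainty does to the model's external calibration. The headline
finding it reproduces: penalization is *most unreliable exactly when it is
most needed* — small effective sample sizes and apparent Cox–Snell $R^2$ far
below 1.

## Estimators implemented

**Likelihood summaries.** For an ML fit, `likelihood_summary()` records the
likelihood-ratio statistic $LR = 2(\ell_{\text{model}} - \ell_{\text{null}})$
and the Cox–Snell $R^2_{\text{app}} = 1 - \exp(-LR/n)$. For Gaussian ML this
equals the classical $1 - SSE/SST$ (a test asserts the identity to $10^{-8}$
against an OLS fit).

**Heuristic shrinkage.** The Van Houwelingen–Le Cessie closed form
$S_{\text{heur}} = (LR - p)/LR$, equivalently $1 + p /(n \log(1 -
R^2_{\text{app}}))$ — both forms are computed and must agree to $10^{-10}$.
The estimate is *not* truncated to $[0, 1]$ by default (`truncate = TRUE` is
available): values above 1 and even below 0 are genuinely observable in weak
models, and hiding them would hide precisely the instability under study.

**Bootstrap shrinkage.** `bootstrap_shrinkage()` refits the ML model in each
of $B$ bootstrap resamples, evaluates that model's linear predictor on the
*original* data, and takes the calibration slope of the original outcome on
that linear predictor as one draw of $S$. The reported estimate is the mean
over retained draws with a 95% percentile interval (type-7
linear-interpolation quantiles, so intervals are bit-reproducible given the
seed). This is the plain "fit on resample, calibrate on original" variant;
resamples with separated or non-convergent fits are dropped and counted
(`n_failed`), never imputed, because imputing a slope for a degenerate fit
would fabricate information the resample does not contain.

**Applying S.** `apply_shrinkage()` multiplies the coefficients by $S$ and
re-estimates the intercept by ML with the shrunken linear predictor as a fixed
offset. The intercept score equation then forces
$\sum_i \hat p_i = \sum_i y_i$ (logistic) or
$\alpha^* = \bar y - S\,\overline{X\hat\beta}$ (Gaussian, closed form) — the
sense in which calibration-in-the-large is "correct by construction" on the
development data.

**Penalized fits and tuning.** `fit_penalized()` delegates the convex
optimization to glmnet (coordinate descent, predictors standardized
internally to unit population variance, intercept unpenalized, coefficients
returned on the original scale); $\lambda$ is therefore on glmnet's
per-observation scale (mean log-likelihood minus penalty). `lambda_path()`
builds the conventional grid: 100 log-spaced values descending from the
data-derived $\lambda_{\max} = \max_j |x_j^{\top}(y - \bar y)| / (n
\max(\alpha, 0.001))$ down to $10^{-4}\lambda_{\max}$; at the top of a
lasso/elastic-net grid every slope is exactly zero (a test fits there and
checks). `select_lambda_cv()` implements K-fold cross-validation with
outcome-stratified folds (at $n = 100$ with 50 events, unstratified folds
occasionally go single-class), held-out deviance summed within a fold and
averaged across folds, and ties broken toward the larger — more conservative —
$\lambda$. `select_lambda_bootstrap_cv()` repeats the whole CV inside $B$
bootstrap resamples and takes the median chosen $\lambda$.

**Validation.** `validate_model()` transports a model unchanged to an
independent dataset and computes the c-index (midrank formula, identical to
$O(n^2)$ pair enumeration and invariant to monotone transforms of the risk),
the calibration slope (free-intercept logistic regression of outcome on
linear predictor), calibration-in-the-large (intercept with the linear
predictor as offset, slope pinned at 1), and Nagelkerke $R^2$ computed from
the transported likelihood against the validation-data null model — no
refitting, so a model that transports badly can legitimately score below 0.

## The synthetic generator and what it emulates

`sim_scenario()` encodes the study design: a binary outcome at 50% prevalence
and 20 standard-normal predictors — 5 "true" predictors, pairwise correlated
at 0.1, and 15 independent noise predictors — across development sizes 100 to
1,000 (events per parameter 2.5 to 25), with 500 replicate datasets and
validation sets of 5,000 (2,500 expected events) per scenario.

The generating equation behind the published design is not reproduced in the
available text, so its coefficients are this package's own calibrated choice,
made once: **intercept 0** (with symmetric centred predictors this pins
expected prevalence at exactly 0.5), **equal coefficients of 0.5** on the five
true predictors, **exactly 0** on the noise predictors. An effect of 0.5 per
true predictor gives a linear-predictor standard deviation of
$\sqrt{0.25(5 + 20 \times 0.1)} \approx 1.3$, a large-sample c-index around
0.78 and an apparent Cox–Snell $R^2$ in the mid-0.2s at moderate $n$ —
representative of real binary-outcome prognostic models and reproducing the
published regime: substantial overfitting at $n = 100$, mild at $n = 1000$.

`simulate_continuous_fixture()` provides the linear-Gaussian analogue of the
applied examples: $p$ independent standard-normal predictors with a common
slope $b = \sqrt{R^2/((1 - R^2)p)}$ and unit noise variance, so the
*population* $R^2$ is exact by construction. The three regimes used in tests
and the acceptance script — $R^2 \approx 0.23$ with $p = 7$ at $n = 262$,
$\approx 0.56$ with $p = 7$, and $\approx 0.81$ with $p = 4$ at $n = 654$ —
mirror the low/medium/high apparent-$R^2$ blood-pressure and lung-function
models of the applied examples. They are synthetic stand-ins, not those
datasets: they share the $(n, p, R^2)$ geometry but none of the covariate
structure (mixed binary/continuous predictors, collinearity between systolic
and diastolic pressure, and so on). Passing the regime tests therefore shows
the *mechanism* — shrinkage uncertainty is governed by $n$, $p$ and apparent
fit — not agreement with any patient data.

What the generator deliberately omits: missing data, categorical predictors,
model misspecification (the fitted model always nests the truth), and
time-to-event outcomes.

## Seeds and reproducibility

Every stochastic function takes an explicit `seed`. The scenario runner draws
one vector of per-replicate seeds from its master seed, so replicate $i$ is
reproducible in isolation and results are identical whatever the execution
order; a rerun with the same master seed reproduces the results CSV
byte-for-byte (asserted in a test).

## Numerical choices

* glmnet convergence threshold $10^{-12}$ for single-$\lambda$ fits (the
  $\lambda = 0$ fit must match ML to $10^{-6}$ per coefficient; observed
  agreement is about $10^{-8}$), $10^{-10}$ inside cross-validation loops.
* Lasso/elastic-net coefficients below $10^{-12}$ (relative) are snapped to
  exact zero: the absolute-value penalty produces exact zeros mathematically,
  and selection counts should not depend on floating-point dust.
* Held-out probabilities are clamped at $10^{-15}$ before taking logs.
* ML fits use IRLS to $\varepsilon = 10^{-12}$; separation is detected from
  the fitted-probability warning and reported via `converged`, not an error,
  because a separated replicate is itself a datum about small-sample
  instability.
* Degenerate inputs fail loudly: constant outcome, constant linear predictor
  in the calibration regression, single-class c-index input. A
  cross-validation that produces a single-class training fold re-randomizes
  once, then fails.

## Problem sizes used by the test-suite and acceptance script

The shipped experiments run the full study design at reduced replication,
sized so the whole suite completes comfortably on one CPU: 50 replicate
datasets per scenario (the published grid used 500) at $n \in \{100, 1000\}$,
bootstrap shrinkage with $B = 200$ inside the runner and $B = 1000$
standalone, bootstrap-CV with $B = 50$ over 20 outer replicates, and
subsampling ladders of 3–4 sizes with $B = 500$. Directions of the
qualitative findings (interquartile ranges widening as $n$ falls, bootstrap-CV
variance reduction, shrinkage intervals widening down the ladder) are stable
at this replication; exact medians carry Monte-Carlo noise of a few
hundredths.

## Design choices where the design was open

* **Bootstrap-S variant**: the one-slope "fit on the resample, calibrate the
  original data" estimator, the simplest textbook-consistent reading; the
  optimism-corrected two-slope variant would be a drop-in alternative behind
  the same interface.
* **Elastic-net mixing** defaults to $\alpha = 0.5$ (the published analysis
  does not state its value); it is a plain argument everywhere.
* **One fresh validation set per replicate** (configurable via
  `shared_validation`): closer to "a validation set was created" per developed
  model, and it keeps replicates exchangeable.
* **Negative or >1 shrinkage estimates are reported as-is**; truncation is
  opt-in. Confidence intervals crossing 1 are part of the phenomenon.
* **Failures carry reason codes** (`note` column) and summaries are computed
  over successes with failure counts reported; how the published study
  handled such replicates is not stated.

## Known limitations

* A large-sample subtlety the scaled-down study makes visible: with 15
  pure-noise predictors among 20, min-deviance cross-validated lasso and
  elastic net over-shrink the five true effects, leaving their median
  external calibration slope near 1.1 even at $n = 1000$ (2,500 events). The
  same behaviour is produced by `cv.glmnet`'s `lambda.min` on identical data,
  so it is a property of deviance-optimal tuning in sparse-truth designs, not
  of this implementation. Symmetrically, raw ML still sits near 0.90 at
  $n = 1000$ under this generator. "Calibration slope approaches 1 as $n$
  grows" should therefore be read as *into the 0.8–1.2 band*, not to 1
  exactly.
* The penalized-likelihood machinery covers binary and Gaussian outcomes
  only; no survival models, no grouped or adaptive penalties, no
  information-criterion tuning.
* The c-index is computed for binary outcomes; continuous-outcome validation
  reports calibration and $R^2$ quantities only.

## A worked run

```{r example, eval = FALSE}
sc <- sim_scenario(n_dev = 100) # 50 events, 20 parameters: EPP 2.5
res <- run_scenario(sc, seed = 1, n_sim = 50, n_boot_shrink = 200)
summarize_results(res) |>
  filter(quantity == "cal_slope")
autoplot(res, metric = "cal_slope")

# shrinkage uncertainty in an applied-example regime
d <- simulate_continuous_fixture(262, p = 7, target_r2 = 0.23, seed = 1)
bootstrap_shrinkage(d, n_boot = 1000, seed = 2)
```

All quantitative statements above are recomputed, not quoted: the test suite
(`tests/testthat/`) asserts the identities and qualitative findings, and
`scripts/acceptance.R` re-derives the headline numbers from scratch at any
seed.
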