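# shrinkstab

Shrinkage and penalization are the standard prescriptions against overfitting
when developing clinical prediction models: multiply the maximum-likelihood
predictor effects by a uniform shrinkage factor *S*, or penalize during
estimation (ridge, lasso, elastic net) with a tuning parameter λ. But *S* and
λ must themselves be estimated from the development data, and in small
effective samples those estimates are wildly uncertain — so the "fixed" model
can be just as miscalibrated in new patients as the naive one. `shrinkstab`
is a toolkit for quantifying that instability, aimed at biostatisticians and
methodologists studying prediction-model development.

## What it computes

For a logistic model
`logit(p̂ᵢ) = α* + S(β̂₁x₁ᵢ + β̂₂x₂ᵢ + …)`:

* **Heuristic shrinkage** — the Van Houwelingen–Le Cessie closed form
  `S = (LR − p)/LR ≡ 1 + p/(n·log(1 − R²_CS))`, where `LR` is the
  likelihood-ratio statistic, `p` the predictor count and
  `R²_CS = 1 − exp(−LR/n)` the apparent Cox–Snell R².
* **Bootstrap shrinkage** — refit on each bootstrap resample, take the
  calibration slope of the original outcome on the resample model's linear
  predictor; mean plus 95% percentile interval over B draws.
* **Penalized regression** — ridge / lasso / elastic-net logistic (and
  Gaussian) fits with λ chosen by stratified K-fold cross-validation
  minimizing held-out deviance, or by bootstrap K-fold CV (median chosen λ
  over B resamples).
* **External validation** — c-index, Nagelkerke R², calibration-in-the-large
  and calibration slope for any fitted model on independent data.
* **A seeded Monte-Carlo study runner** — the full design (binary outcome at
  50% prevalence; 20 standard-normal predictors of which 5 are true with
  pairwise correlation 0.1; development n from 100 to 1,000; validation sets
  of 5,000) across six development methods, summarized as medians and
  percentile spreads, with ggplot2 `autoplot()` displays.

Everything is data-frame-in / tibble-out and pipe-friendly, with
broom-style `tidy()` / `glance()` methods on every result object.

## Worked example

How uncertain is the shrinkage factor for a model with apparent R² ≈ 0.23,
seven predictors and 262 participants?

```r
library(shrinkstab)
d <- simulate_continuous_fixture(262, p = 7, target_r2 = 0.23, seed = 1)
bootstrap_shrinkage(d, n_boot = 1000, seed = 2)
#> <boot_shrinkage> uniform shrinkage factor S from 1000 bootstrap samples (n = 262, p = 7)
#>   mean S = 0.914  95% CI [0.713, 1.194]
```

The point estimate says "shrink effects by ~9%", but the 95% interval runs
from heavy shrinkage (0.71) to *expansion* (1.19): the data cannot tell you
the right amount of shrinkage. The same instability propagates into
penalized methods — at 50 events for 20 candidate parameters (events per
parameter 2.5), external calibration of every method is all over the place:

```r
sc <- sim_scenario(n_dev = 100)   # 50 expected events, 20 parameters
res <- run_scenario(sc, seed = 1, n_sim = 10, n_boot_shrink = 200)
summarize_results(res) |> dplyr::filter(quantity == "cal_slope")
#> # A tibble: 6 × 10
#>   n_dev method           quantity   n_ok n_failed median  q025   q25   q75  q975
#>   <dbl> <chr>            <chr>     <int>    <int>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1   100 bootstrap_shrink cal_slope    10        0  0.978 0.617 0.808 1.18  1.44
#> 2   100 elastic_net      cal_slope    10        0  1.45  0.751 1.01  1.77  2.08
#> 3   100 heuristic_shrink cal_slope    10        0  0.616 0.353 0.507 0.793 1.20
#> 4   100 lasso            cal_slope    10        0  1.29  0.696 0.987 1.65  3.40
#> 5   100 mle              cal_slope    10        0  0.377 0.257 0.299 0.443 0.535
#> 6   100 ridge            cal_slope    10        0  1.28  0.775 1.05  1.56  1.76
```

A calibration slope of 1 is ideal; here the raw ML model's median slope is
0.38 (predictions far too extreme) and the penalized methods scatter from
0.7 to above 2 across replicate datasets drawn from the *same* population.
`autoplot(res, metric = "cal_slope")` draws the corresponding boxplots. At
`n_dev = 1000` (events per parameter 25) the same pipeline produces slopes
tightly clustered near 1 for every method.

See the vignette (`vignettes/shrinkage-instability.Rmd`) for the model,
estimators, generator calibration and numerical choices.

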