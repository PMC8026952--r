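#' Concordance index (c-statistic)
#'
#' The probability that a randomly chosen event has a higher predicted risk
#' than a randomly chosen non-event, with ties counted one half. Computed
#' from rank statistics (midranks handle ties), so it is invariant to any
#' monotone transform of the risks — the linear predictor and the predicted
#' probability give the same value.
#'
#' @param y Binary 0/1 outcomes; both classes must be present.
#' @param risk Predicted risks or linear predictors, same length as `y`.
#' @return The concordance probability in `[0, 1]`.
#' @examples
#' c_index(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)) # 0.75
#' @export
c_index <- function(y, risk) {
  stopifnot(length(y) == length(risk), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("c-index needs both events and non-events in `y`", call. = FALSE)
  }
  r <- rank(risk) # midranks: tied pairs contribute 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope
#'
#' Slope from regressing the observed outcomes on the model's linear
#' predictor in the validation data (logistic regression for a binary
#' outcome, least squares for a continuous one), with a free intercept.
#' 1 is ideal; values below 1 mean the predictions are too extreme
#' (overfitted); above 1, too timid.
#'
#' @param y Validation outcomes.
#' @param lp The model's linear predictor on the validation data.
#' @param family `"binary"` or `"continuous"`.
#' @return The calibration slope.
#' @export
calibration_slope <- function(y, lp, family = "binary") {
  check_outcome(y, family)
  if (stats::sd(lp) == 0) {
    stop("the linear predictor is constant; the calibration slope is not ",
         "identified (the model makes the same prediction for everyone)",
         call. = FALSE)
  }
  fit <- ml_fit(matrix(lp, ncol = 1), y, family)
  unname(fit$coef[2])
}

#' Calibration-in-the-large
#'
#' Intercept of the regression of validation outcomes on the linear
#' predictor entered as a fixed offset (slope held at 1). 0 means the
#' predictions are correct on average; negative values mean the model
#' over-predicts.
#'
#' @inheritParams calibration_slope
#' @return The calibration-in-the-large intercept.
#' @export
calibration_in_the_large <- function(y, lp, family = "binary") {
  check_outcome(y, family)
  if (family == "continuous") return(mean(y) - mean(lp))
  fit <- stats::glm.fit(matrix(1, length(y), 1), y,
                        family = stats::binomial(), offset = lp,
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
  unname(fit$coefficients[1])
}

#' Nagelkerke R-squared
#'
#' The Cox-Snell R-squared rescaled by its maximum attainable value
#' `1 - exp(2 * loglik_null / n)`, so a perfectly predictive model scores 1.
#'
#' @param summary A [likelihood_summary()].
#' @return The scaled R-squared.
#' @export
nagelkerke_r2 <- function(summary) {
  stopifnot(inherits(summary, "lik_summary"))
  max_r2 <- 1 - exp(2 * summary$loglik_null / summary$n)
  if (max_r2 <= 0) {
    stop("maximum attainable Cox-Snell R-squared is 0 (degenerate outcome)",
         call. = FALSE)
  }
  summary$r2_cs / max_r2
}

#' Validate a fitted model on independent data
#'
#' Evaluates a developed model in a validation dataset with the four
#' standard external-validation metrics: c-index, Nagelkerke R-squared,
#' calibration-in-the-large, and calibration slope. The model is
#' transported as-is — its linear predictor is computed on the validation
#' rows and never refitted — and the Nagelkerke value uses the transported
#' likelihood against the validation-data null model, so a model that
#' predicts worse than the null can score below 0.
#'
#' @param fit A `cpm_fit`.
#' @param newdata The validation data frame (predictors plus `y`).
#' @return A one-row tibble of class `validation_result` with columns
#'   `method`, `c_index`, `nagelkerke_r2`, `citl`, `cal_slope`, `n_val`.
#' @examples
#' sc <- sim_scenario(n_dev = 200)
#' dev <- simulate_binary(sc, seed = 1)
#' val <- simulate_binary(sc, n = 2000, seed = 2)
#' validate_model(fit_mle(dev), val)
#' @export
validate_model <- function(fit, newdata) {
  stopifnot(inherits(fit, "cpm_fit"))
  y <- newdata$y
  family <- fit$family
  check_outcome(y, family)
  lp <- predict(fit, newdata, type = "link")
  n <- length(y)
  ll_model <- loglik_at(y, lp, family)
  ll_null <- loglik_at(y, rep(null_link(y, family), n), family)
  lr <- 2 * (ll_model - ll_null) # transported model: may be negative
  summ <- tibble::tibble(loglik_null = ll_null, loglik_model = ll_model,
                         n = n, p = length(fit$coefficients),
                         lr = lr, r2_cs = 1 - exp(-lr / n))
  class(summ) <- c("lik_summary", class(summ))
  out <- tibble::tibble(
    method = fit$method,
    c_index = if (family == "binary") c_index(y, lp) else NA_real_,
    nagelkerke_r2 = nagelkerke_r2(summ),
    citl = calibration_in_the_large(y, lp, family),
    cal_slope = calibration_slope(y, lp, family),
    n_val = n
  )
  class(out) <- c("validation_result", class(out))
  out
}
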