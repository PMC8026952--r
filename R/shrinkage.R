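#' Likelihood summary of a maximum-likelihood fit
#'
#' Computes the log-likelihoods of the fitted and the intercept-only model,
#' the likelihood-ratio statistic `LR = 2 (loglik_model - loglik_null)` and
#' the Cox-Snell R-squared `1 - exp(-LR / n)`. For a Gaussian
#' maximum-likelihood fit the Cox-Snell value reduces to the classical
#' R-squared `1 - SSE/SST`.
#'
#' @param data The development data the model was fitted on.
#' @param fit A `cpm_fit` obtained by unpenalized maximum likelihood on
#'   `data`.
#' @return A one-row tibble of class `lik_summary` with columns
#'   `loglik_null`, `loglik_model`, `n`, `p`, `lr`, `r2_cs`.
#' @examples
#' d <- simulate_binary(sim_scenario(n_dev = 300), seed = 1)
#' likelihood_summary(d, fit_mle(d))
#' @export
likelihood_summary <- function(data, fit) {
  stopifnot(inherits(fit, "cpm_fit"))
  y <- data$y
  n <- length(y)
  family <- fit$family
  check_outcome(y, family)
  lp <- predict(fit, data, type = "link")
  ll_model <- loglik_at(y, lp, family)
  ll_null <- loglik_at(y, rep(null_link(y, family), n), family)
  lr <- max(0, 2 * (ll_model - ll_null))
  out <- tibble::tibble(
    loglik_null = ll_null, loglik_model = ll_model,
    n = n, p = length(fit$coefficients),
    lr = lr, r2_cs = 1 - exp(-lr / n)
  )
  class(out) <- c("lik_summary", class(out))
  out
}

null_link <- function(y, family) {
  if (family == "binary") stats::qlogis(mean(y)) else mean(y)
}

# log-likelihood of outcomes under fixed linear predictors; Gaussian uses
# the profile (ML) error variance so LR statistics are likelihood ratios
loglik_at <- function(y, lp, family) {
  n <- length(y)
  if (family == "binary") {
    p <- stats::plogis(lp)
    eps <- 1e-15
    sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  } else {
    sse <- sum((y - lp)^2)
    -n / 2 * (log(2 * pi * sse / n) + 1)
  }
}

#' Closed-form (heuristic) uniform shrinkage factor
#'
#' The Van Houwelingen-Le Cessie heuristic `S = (LR - p) / LR`, where `LR`
#' is the model's likelihood-ratio statistic and `p` its number of predictor
#' parameters. Because `R2_CS = 1 - exp(-LR/n)`, this is algebraically
#' identical to `1 + p / (n * log(1 - R2_CS))`, which makes explicit that
#' the estimate moves away from 1 as the apparent Cox-Snell R-squared
#' falls. For very weak models the value can be negative; it is returned
#' as-is with a warning unless `truncate = TRUE`.
#'
#' @param summary A [likelihood_summary()].
#' @param truncate If `TRUE`, clamp the estimate to `[0, 1]`.
#' @return A single shrinkage value.
#' @examples
#' d <- simulate_binary(sim_scenario(n_dev = 300), seed = 1)
#' heuristic_shrinkage(likelihood_summary(d, fit_mle(d)))
#' @export
heuristic_shrinkage <- function(summary, truncate = FALSE) {
  stopifnot(inherits(summary, "lik_summary"))
  lr <- summary$lr
  p <- summary$p
  if (p == 0) return(1)
  if (lr <= 0) {
    stop("the likelihood-ratio statistic is 0; the heuristic shrinkage ",
         "factor (LR - p)/LR is undefined", call. = FALSE)
  }
  s <- (lr - p) / lr
  if (s < 0 && !truncate) {
    warning("heuristic shrinkage estimate is negative (", signif(s, 3),
            "): the model fits worse than its parameter count", call. = FALSE)
  }
  if (truncate) s <- min(1, max(0, s))
  s
}

new_boot_shrinkage <- function(s_samples, n_boot, n_failed, n, p, family) {
  ci <- stats::quantile(s_samples, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(s_mean = mean(s_samples), s_samples = s_samples,
         ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, n_failed = n_failed, n = n, p = p,
         family = family),
    class = "boot_shrinkage"
  )
}

#' @export
print.boot_shrinkage <- function(x, ...) {
  cat("<boot_shrinkage> uniform shrinkage factor S from ",
      x$n_boot, " bootstrap samples (n = ", x$n, ", p = ", x$p, ")\n",
      "  mean S = ", sprintf("%.3f", x$s_mean),
      "  95% CI [", sprintf("%.3f", x$ci_low), ", ",
      sprintf("%.3f", x$ci_high), "]\n", sep = "")
  if (x$n_failed > 0) {
    cat("  ", x$n_failed, " replicates dropped (non-convergence)\n")
  }
  invisible(x)
}

#' Bootstrap estimate of the uniform shrinkage factor
#'
#' For each of `n_boot` bootstrap resamples (with replacement, size n): fit
#' the unpenalized model on the resample, compute its linear predictor on
#' the *original* data, and regress the original outcome on that linear
#' predictor (same family). The slope is one bootstrap shrinkage value; the
#' estimate of S is the mean over retained replicates, with a 95% percentile
#' confidence interval from the empirical 2.5th and 97.5th percentiles
#' (linear-interpolation order statistics, so results are reproducible
#' bit-for-bit given the seed). Resamples with separated or otherwise
#' non-convergent fits are dropped and counted in `n_failed`.
#'
#' @param data Development data frame with predictors and outcome `y`.
#' @param family `"binary"` or `"continuous"`.
#' @param n_boot Number of bootstrap samples (1,000 by default).
#' @param seed Optional integer seed.
#' @return A `boot_shrinkage` object; see [tidy.boot_shrinkage()] and
#'   [glance.boot_shrinkage()].
#' @examples
#' d <- simulate_continuous_fixture(200, p = 4, target_r2 = 0.8, seed = 1)
#' bootstrap_shrinkage(d, n_boot = 100, seed = 2)
#' @export
bootstrap_shrinkage <- function(data, family = dataset_family(data),
                                n_boot = 1000, seed = NULL) {
  stopifnot(n_boot >= 2)
  x <- predictor_matrix(data)
  y <- data$y
  check_outcome(y, family)
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 2) {
    stop("need at least p + 2 = ", p + 2, " rows to fit and calibrate; got ",
         n, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  s <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (family == "binary" && length(unique(y[idx])) < 2) next
    bf <- ml_fit(x[idx, , drop = FALSE], y[idx], family)
    if (!bf$converged || anyNA(bf$coef)) next
    lp <- bf$coef[1] + drop(x %*% bf$coef[-1])
    if (stats::sd(lp) == 0) next
    cal <- ml_fit(matrix(lp, ncol = 1), y, family)
    if (!cal$converged || anyNA(cal$coef)) next
    s[b] <- cal$coef[2]
  }
  keep <- s[!is.na(s)]
  if (!length(keep)) {
    stop("all ", n_boot, " bootstrap replicates failed to converge",
         call. = FALSE)
  }
  new_boot_shrinkage(keep, n_boot, n_boot - length(keep), n, p, family)
}

#' Apply a uniform shrinkage factor to a fitted model
#'
#' Multiplies every predictor coefficient by `s` and re-estimates the
#' intercept by maximum likelihood with the shrunken linear predictor
#' (excluding the intercept) held as a fixed offset. This guarantees correct
#' calibration-in-the-large on the development data: for a logistic model
#' the sum of predicted probabilities equals the number of observed events;
#' for a Gaussian model the new intercept is
#' `mean(y) - s * mean(X beta-hat)` in closed form.
#'
#' @param fit An unpenalized `cpm_fit` (method `"mle"`).
#' @param s The shrinkage factor to apply.
#' @param data The development data (used to re-estimate the intercept).
#' @param method Method label for the returned fit, e.g.
#'   `"heuristic_shrunk"` or `"bootstrap_shrunk"`.
#' @return A `cpm_fit` with shrunken coefficients and updated intercept.
#' @export
apply_shrinkage <- function(fit, s, data, method = "heuristic_shrunk") {
  stopifnot(inherits(fit, "cpm_fit"), length(s) == 1, is.finite(s))
  x <- predictor_matrix(data)[, names(fit$coefficients), drop = FALSE]
  y <- data$y
  lp_noint <- drop(x %*% fit$coefficients)
  new_beta <- s * fit$coefficients
  if (fit$family == "continuous") {
    alpha_star <- mean(y) - s * mean(lp_noint)
  } else {
    off <- s * lp_noint
    refit <- stats::glm.fit(matrix(1, length(y), 1), y,
                            family = stats::binomial(), offset = off,
                            control = stats::glm.control(epsilon = 1e-12,
                                                         maxit = 100))
    alpha_star <- refit$coefficients[1]
  }
  out <- new_cpm_fit(alpha_star, new_beta, fit$family, method,
                     converged = fit$converged)
  out$s <- s
  out
}
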