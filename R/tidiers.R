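#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted prediction model
#'
#' @param x A `cpm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`).
#' @method tidy cpm_fit
#' @export
tidy.cpm_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.cpm_fit
#' @return `glance` returns a one-row tibble with the method, family,
#'   tuning metadata, nonzero-coefficient count and convergence flag.
#' @method glance cpm_fit
#' @export
glance.cpm_fit <- function(x, ...) {
  tibble::tibble(method = x$method, family = x$family, lambda = x$lambda,
                 alpha_mix = x$alpha_mix,
                 n_nonzero = sum(x$coefficients != 0),
                 converged = x$converged)
}

#' Tidy a bootstrap shrinkage estimate
#'
#' @param x A `boot_shrinkage`.
#' @param ... Unused.
#' @return `tidy` returns the retained bootstrap shrinkage values, one row
#'   each; `glance` the one-row summary (mean, percentile CI, counts).
#' @method tidy boot_shrinkage
#' @export
tidy.boot_shrinkage <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$s_samples), s = x$s_samples)
}

#' @rdname tidy.boot_shrinkage
#' @method glance boot_shrinkage
#' @export
glance.boot_shrinkage <- function(x, ...) {
  tibble::tibble(s_mean = x$s_mean, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_boot = x$n_boot, n_failed = x$n_failed,
                 n = x$n, p = x$p, family = x$family)
}

#' Tidy a tuning-parameter selection
#'
#' @param x A `lambda_cv`.
#' @param ... Unused.
#' @return `tidy` returns the cross-validation curve (`lambda`,
#'   `cv_deviance`) for the plain variant, or the per-bootstrap chosen
#'   lambdas for the bootstrap variant; `glance` the one-row selection
#'   summary.
#' @method tidy lambda_cv
#' @export
tidy.lambda_cv <- function(x, ...) {
  if (x$n_boot > 0) {
    tibble::tibble(replicate = seq_along(x$per_boot_lambdas),
                   lambda = x$per_boot_lambdas)
  } else {
    tibble::tibble(lambda = x$lambda_grid, cv_deviance = x$cv_deviance)
  }
}

#' @rdname tidy.lambda_cv
#' @method glance lambda_cv
#' @export
glance.lambda_cv <- function(x, ...) {
  tibble::tibble(chosen_lambda = x$chosen_lambda, k_folds = x$k_folds,
                 n_boot = x$n_boot, n_failed = x$n_failed,
                 n_lambda = length(x$lambda_grid))
}

#' Summary of a prediction-difference experiment
#'
#' @param x A `pred_diff` tibble from [prediction_difference()].
#' @param ... Unused.
#' @return A one-row tibble: shrinkage interval, threshold, number and
#'   proportion of individuals whose prediction moves by more than the
#'   threshold, and the largest absolute difference.
#' @method glance pred_diff
#' @export
glance.pred_diff <- function(x, ...) {
  tibble::tibble(s_low = attr(x, "s_low"), s_high = attr(x, "s_high"),
                 threshold = attr(x, "threshold"),
                 n = nrow(x), n_exceed = sum(x$exceeds),
                 prop_exceed = mean(x$exceeds),
                 max_abs_diff = max(x$abs_diff))
}
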