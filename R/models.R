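fam_obj <- function(family) {
  switch(family,
         binary = stats::binomial(),
         continuous = stats::gaussian(),
         stop("unknown family: ", family, call. = FALSE))
}

check_outcome <- function(y, family) {
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  if (family == "binary") {
    if (!all(y %in% c(0, 1))) {
      stop("binary family requires a 0/1 outcome", call. = FALSE)
    }
    if (length(unique(y)) < 2) {
      stop("degenerate outcome: `y` is constant, the intercept is not ",
           "identified", call. = FALSE)
    }
  } else if (stats::sd(y) == 0) {
    stop("degenerate outcome: `y` is constant", call. = FALSE)
  }
  invisible(y)
}

# glmnet requires at least two predictor columns; for p = 1 we carry a
# constant zero column whose coefficient is identically zero and strip it
pad_single_column <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad.` = 0)
}

new_cpm_fit <- function(intercept, coefficients, family, method,
                        lambda = NA_real_, alpha_mix = NA_real_,
                        converged = TRUE) {
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         family = family, method = method, lambda = lambda,
         alpha_mix = alpha_mix, converged = converged),
    class = "cpm_fit"
  )
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat("<cpm_fit> ", x$method, " (", x$family, " family)\n", sep = "")
  if (!is.na(x$lambda)) cat("  lambda =", signif(x$lambda, 4), "\n")
  cat("  intercept =", signif(x$intercept, 4), "\n")
  nz <- sum(x$coefficients != 0)
  cat("  coefficients:", length(x$coefficients), "(", nz, "nonzero )\n")
  if (!x$converged) cat("  [fit flagged as non-converged]\n")
  invisible(x)
}

#' Predict from a fitted prediction model
#'
#' @param object A `cpm_fit`.
#' @param newdata Data frame containing the model's predictor columns.
#' @param type `"link"` for the linear predictor, `"response"` for the
#'   predicted probability (binary) or mean (continuous).
#' @param ... Unused.
#' @return A numeric vector, one value per row of `newdata`.
#' @export
predict.cpm_fit <- function(object, newdata,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  nm <- names(object$coefficients)
  missing_cols <- setdiff(nm, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks predictor columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[nm])
  lp <- object$intercept + drop(x %*% object$coefficients)
  if (type == "link" || object$family == "continuous") lp
  else stats::plogis(lp)
}

# IRLS/OLS fit via stats::glm.fit on a precomputed design matrix, with
# separation detected from the usual fitted-probability warning.
ml_fit <- function(x, y, family, offset = NULL) {
  fam <- fam_obj(family)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), y, family = fam,
                   offset = offset,
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  list(coef = fit$coefficients, converged = fit$converged && !separated,
       separated = separated)
}

#' Fit an unpenalized regression model by maximum likelihood
#'
#' Logistic regression for a binary outcome, ordinary least squares
#' (Gaussian maximum likelihood) for a continuous one. Perfect separation is
#' reported through the `converged` flag rather than an error.
#'
#' @param data Data frame with predictor columns and outcome column `y`.
#' @param family `"binary"` or `"continuous"`; inferred from the data when
#'   omitted.
#' @return A `cpm_fit` with method `"mle"`.
#' @examples
#' d <- simulate_binary(sim_scenario(n_dev = 200), seed = 1)
#' fit_mle(d)
#' @export
fit_mle <- function(data, family = dataset_family(data)) {
  x <- predictor_matrix(data)
  y <- data$y
  check_outcome(y, family)
  if (nrow(x) <= ncol(x)) {
    warning("n (", nrow(x), ") does not exceed p (", ncol(x),
            "); maximum-likelihood estimates will be unstable",
            call. = FALSE)
  }
  fit <- ml_fit(x, y, family)
  new_cpm_fit(fit$coef[1], fit$coef[-1], family, "mle",
              converged = fit$converged)
}

#' Fit a penalized regression model at a fixed tuning value
#'
#' Maximizes the mean per-observation log-likelihood minus
#' `lambda * (alpha_mix * sum(|b|) + (1 - alpha_mix)/2 * sum(b^2))`
#' on internally standardized predictors (the glmnet convention; the
#' intercept is never penalized), returning coefficients on the original
#' scale. `alpha_mix = 0` is ridge, `1` is the lasso, values between are the
#' elastic net. `lambda = 0` recovers the maximum-likelihood fit.
#'
#' @param data Data frame with predictors and outcome `y`.
#' @param lambda Nonnegative penalty weight.
#' @param alpha_mix Elastic-net mixing in `[0, 1]`.
#' @param family `"binary"` or `"continuous"`.
#' @param method Method label stored on the fit.
#' @return A `cpm_fit`.
#' @export
fit_penalized <- function(data, lambda, alpha_mix = 0.5,
                          family = dataset_family(data),
                          method = NULL) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  if (alpha_mix < 0 || alpha_mix > 1) {
    stop("`alpha_mix` must lie in [0, 1]", call. = FALSE)
  }
  x <- predictor_matrix(data)
  y <- data$y
  check_outcome(y, family)
  # solve along a decreasing path ending at the requested lambda so the
  # coordinate-descent warm starts give an accurate solution there
  grid <- lambda_path(data, alpha_mix = alpha_mix, family = family)
  grid <- sort(unique(c(grid[grid > lambda], lambda)), decreasing = TRUE)
  if (length(grid) < 2) grid <- c(max(1.5 * lambda, 1e-3), lambda)
  gfam <- if (family == "binary") "binomial" else "gaussian"
  padded <- ncol(x) < 2
  fit <- glmnet::glmnet(pad_single_column(x), y, family = gfam,
                        alpha = alpha_mix, lambda = grid,
                        standardize = TRUE, thresh = 1e-12, maxit = 1e6)
  k <- which.min(abs(fit$lambda - lambda))
  beta <- as.numeric(fit$beta[, k])
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[colnames(x)]
  if (alpha_mix > 0) {
    # absolute-value penalties produce exact zeros; drop float dust so
    # selection counts are exact
    beta[abs(beta) < 1e-12 * max(1, max(abs(beta)))] <- 0
  }
  if (is.null(method)) {
    method <- if (alpha_mix == 0) "ridge"
              else if (alpha_mix == 1) "lasso" else "elastic_net"
  }
  new_cpm_fit(fit$a0[k], beta, family, method, lambda = lambda,
              alpha_mix = alpha_mix)
}

#' Data-derived tuning-parameter grid
#'
#' A log-spaced descending grid of `n_lambda` values from the data-derived
#' maximum down to `lambda_min_ratio` times it. For the lasso and elastic
#' net the maximum is the smallest lambda at which every slope is exactly
#' zero, `max|x_std' (y - mean(y))| / (n * max(alpha_mix, 0.001))`;
#' for ridge (`alpha_mix = 0`) the same formula applies with the
#' conventional floor of 0.001 on the mixing weight, i.e. 1,000 times the
#' lasso maximum.
#'
#' @inheritParams fit_penalized
#' @param n_lambda Grid size.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value.
#' @return A numeric vector of strictly decreasing positive lambdas.
#' @export
lambda_path <- function(data, alpha_mix = 0.5, n_lambda = 100,
                        lambda_min_ratio = 1e-4,
                        family = dataset_family(data)) {
  stopifnot(n_lambda >= 2)
  x <- predictor_matrix(data)
  y <- data$y
  check_outcome(y, family)
  n <- nrow(x)
  # population-variance standardization, matching glmnet's internal scaling
  xs <- scale(x, center = TRUE, scale = apply(x, 2, function(c) {
    sqrt(mean((c - mean(c))^2))
  }))
  r <- y - mean(y)
  lmax <- max(abs(crossprod(xs, r))) / (n * max(alpha_mix, 0.001))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Stratified fold assignment: shuffled indices of each outcome class are
# concatenated and folds dealt cyclically over the concatenation, so every
# fold is non-empty (k <= n) and the class mix per fold is within one
# observation of proportional. Continuous outcomes get plain random folds.
make_folds <- function(y, k, family) {
  n <- length(y)
  fold <- integer(n)
  shuf <- function(v) if (length(v) <= 1L) v else sample(v)
  idx <- if (family == "binary") {
    c(shuf(which(y == 1)), shuf(which(y == 0)))
  } else {
    sample(n)
  }
  fold[idx] <- rep_len(seq_len(k), n)
  fold
}

heldout_deviance <- function(y, lp, family) {
  if (family == "binary") {
    p <- stats::plogis(lp)
    eps <- 1e-15
    -2 * sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  } else {
    sum((y - lp)^2)
  }
}

new_lambda_cv <- function(grid, dev, chosen, k_folds, n_boot = 0L,
                          per_boot = numeric(0), n_failed = 0L) {
  structure(
    list(lambda_grid = grid, cv_deviance = dev, chosen_lambda = chosen,
         k_folds = k_folds, n_boot = n_boot, per_boot_lambdas = per_boot,
         n_failed = n_failed),
    class = "lambda_cv"
  )
}

#' @export
print.lambda_cv <- function(x, ...) {
  cat("<lambda_cv> ", if (x$n_boot > 0) "bootstrap " else "",
      x$k_folds, "-fold cross-validation over ", length(x$lambda_grid),
      " lambdas\n  chosen lambda = ", signif(x$chosen_lambda, 4), "\n",
      sep = "")
  if (x$n_boot > 0) {
    cat("  median over", x$n_boot - x$n_failed, "bootstrap replicates",
        if (x$n_failed > 0) paste0("(", x$n_failed, " failed)"), "\n")
  }
  invisible(x)
}

cv_deviance_curve <- function(x, y, grid, alpha_mix, k_folds, family) {
  gfam <- if (family == "binary") "binomial" else "gaussian"
  for (attempt in 1:2) {
    fold <- make_folds(y, k_folds, family)
    bad <- family == "binary" &&
      any(vapply(seq_len(k_folds),
                 function(f) length(unique(y[fold != f])) < 2, logical(1)))
    if (!bad) break
    if (attempt == 2) {
      stop("cross-validation produced a single-class training fold twice; ",
           "sample too small for ", k_folds, " folds", call. = FALSE)
    }
  }
  dev <- matrix(NA_real_, k_folds, length(grid))
  xp <- pad_single_column(x)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fit <- glmnet::glmnet(xp[tr, , drop = FALSE], y[tr], family = gfam,
                          alpha = alpha_mix, lambda = grid,
                          standardize = TRUE, thresh = 1e-10, maxit = 1e6)
    lp <- stats::predict(fit, xp[!tr, , drop = FALSE], s = grid,
                         type = "link")
    dev[f, ] <- vapply(seq_along(grid),
                       function(j) heldout_deviance(y[!tr], lp[, j], family),
                       numeric(1))
  }
  colMeans(dev)
}

#' Select the tuning parameter by K-fold cross-validation
#'
#' Folds are stratified by outcome class. For each grid value the held-out
#' deviance (-2 times the held-out log-likelihood, summed within a fold) is
#' averaged over folds; the chosen lambda minimizes this curve, with ties
#' broken toward the larger (more conservative) lambda.
#'
#' @inheritParams fit_penalized
#' @param k_folds Number of folds (the study used 5).
#' @param n_lambda Grid size passed to [lambda_path()].
#' @param grid Optional explicit lambda grid (descending); overrides
#'   `n_lambda`.
#' @param seed Optional integer seed for the fold assignment.
#' @return A `lambda_cv` object; see [tidy.lambda_cv()] for the deviance
#'   curve and [glance.lambda_cv()] for the selection summary.
#' @examples
#' d <- simulate_binary(sim_scenario(n_dev = 200), seed = 1)
#' sel <- select_lambda_cv(d, alpha_mix = 1, seed = 2)
#' sel$chosen_lambda
#' @export
select_lambda_cv <- function(data, alpha_mix = 0.5, k_folds = 5,
                             n_lambda = 100, grid = NULL, seed = NULL,
                             family = dataset_family(data)) {
  stopifnot(k_folds >= 2)
  x <- predictor_matrix(data)
  y <- data$y
  check_outcome(y, family)
  if (is.null(grid)) {
    grid <- lambda_path(data, alpha_mix = alpha_mix, n_lambda = n_lambda,
                        family = family)
  }
  if (!is.null(seed)) set.seed(seed)
  dev <- cv_deviance_curve(x, y, grid, alpha_mix, k_folds, family)
  # grid is descending, so the first minimizer is the largest such lambda
  chosen <- grid[which.min(dev)]
  new_lambda_cv(grid, dev, chosen, k_folds)
}

#' Select the tuning parameter by bootstrap K-fold cross-validation
#'
#' Runs [select_lambda_cv()] inside each of `n_boot` bootstrap resamples of
#' the data (all on the lambda grid derived from the full data) and takes
#' the median of the chosen lambdas. Bootstrap replicates whose
#' cross-validation fails (e.g. a single-class fold in a tiny resample) are
#' dropped and counted.
#'
#' @inheritParams select_lambda_cv
#' @param n_boot Number of bootstrap resamples (the study used 200).
#' @return A `lambda_cv` object with `per_boot_lambdas` filled in and
#'   `chosen_lambda` equal to their median.
#' @export
select_lambda_bootstrap_cv <- function(data, alpha_mix = 0.5, n_boot = 200,
                                       k_folds = 5, n_lambda = 100,
                                       seed = NULL,
                                       family = dataset_family(data)) {
  stopifnot(n_boot >= 1, k_folds >= 2)
  x <- predictor_matrix(data)
  y <- data$y
  check_outcome(y, family)
  grid <- lambda_path(data, alpha_mix = alpha_mix, n_lambda = n_lambda,
                      family = family)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  chosen <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    chosen[b] <- tryCatch({
      dev <- cv_deviance_curve(x[idx, , drop = FALSE], y[idx], grid,
                               alpha_mix, k_folds, family)
      grid[which.min(dev)]
    }, error = function(e) NA_real_)
  }
  ok <- chosen[!is.na(chosen)]
  if (!length(ok)) {
    stop("all ", n_boot, " bootstrap cross-validation replicates failed",
         call. = FALSE)
  }
  new_lambda_cv(grid, rep(NA_real_, length(grid)),
                stats::median(ok), k_folds, n_boot = n_boot,
                per_boot = ok, n_failed = n_boot - length(ok))
}

#' Serialize or restore a fitted model as JSON
#'
#' A `cpm_fit` round-trips through a flat JSON record (intercept, named
#' coefficients, family, method, lambda, alpha_mix, converged) so developed
#' models can be handed between pipeline stages or stored next to result
#' tables.
#'
#' @param fit A `cpm_fit`.
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   the restored `cpm_fit`.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "cpm_fit"))
  rec <- list(intercept = fit$intercept,
              coefficients = as.list(fit$coefficients),
              family = fit$family, method = fit$method,
              lambda = fit$lambda, alpha_mix = fit$alpha_mix,
              converged = fit$converged)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_cpm_fit(rec$intercept, unlist(rec$coefficients), rec$family,
              rec$method,
              lambda = if (is.null(rec$lambda)) NA_real_ else rec$lambda,
              alpha_mix = if (is.null(rec$alpha_mix)) NA_real_
                          else rec$alpha_mix,
              converged = rec$converged)
}
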