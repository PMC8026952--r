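#' Define a binary-outcome simulation scenario
#'
#' A scenario describes one cell of the Monte-Carlo study design: a
#' development sample of `n_dev` participants with a binary outcome at
#' `event_prop` prevalence and `n_predictors` standard-normal predictors, of
#' which `n_true` carry signal and are pairwise correlated at `rho_true`
#' while the rest are independent noise. The default settings (20 predictors,
#' 5 true with correlation 0.1, 50% prevalence, 500 replicates, validation
#' sets of 5,000) are the study conditions used throughout the package.
#'
#' @param n_dev Development sample size (the study varied 100 to 1,000).
#' @param event_prop Target outcome prevalence; 0.5 gives `n_dev/2` expected
#'   events. Achieved through the generating intercept (`qlogis(event_prop)`
#'   when predictors are centred).
#' @param n_predictors Total number of candidate predictor parameters.
#' @param n_true Number of predictors with nonzero generating coefficients.
#' @param rho_true Pairwise correlation among the true predictors.
#' @param effect_size Generating coefficient shared by the true predictors
#'   (noise predictors have coefficient exactly 0).
#' @param n_sim Number of replicate development datasets.
#' @param n_val Size of each independent validation dataset.
#'
#' @return An object of class `sim_scenario`.
#' @examples
#' sc <- sim_scenario(n_dev = 100)
#' events_per_parameter(sc) # 2.5 events per candidate parameter
#' @export
sim_scenario <- function(n_dev = 100, event_prop = 0.5, n_predictors = 20,
                         n_true = 5, rho_true = 0.1, effect_size = 0.5,
                         n_sim = 500, n_val = 5000) {
  stopifnot(n_dev >= 2, n_val >= 2, n_sim >= 1)
  if (n_true > n_predictors) {
    stop("`n_true` (", n_true, ") cannot exceed `n_predictors` (",
         n_predictors, ")", call. = FALSE)
  }
  if (rho_true < 0 || rho_true >= 1) {
    stop("`rho_true` must lie in [0, 1); got ", rho_true, call. = FALSE)
  }
  if (event_prop <= 0 || event_prop >= 1) {
    stop("`event_prop` must lie strictly between 0 and 1", call. = FALSE)
  }
  # block-correlation matrix must be positive definite; for an equicorrelated
  # block of size k this requires rho > -1/(k-1), always true for rho >= 0
  structure(
    list(n_dev = n_dev, event_prop = event_prop,
         n_predictors = n_predictors, n_true = n_true,
         n_noise = n_predictors - n_true, rho_true = rho_true,
         effect_size = effect_size, n_sim = n_sim, n_val = n_val),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario: binary outcome, prevalence ", x$event_prop, "\n",
      "  n_dev = ", x$n_dev, " (", events_per_parameter(x),
      " events per parameter), n_val = ", x$n_val, "\n",
      "  predictors: ", x$n_true, " true (beta = ", x$effect_size,
      ", pairwise r = ", x$rho_true, ") + ", x$n_noise, " noise\n",
      "  replicates: ", x$n_sim, "\n", sep = "")
  invisible(x)
}

#' Events per candidate predictor parameter
#'
#' The crude effective-sample-size gauge for binary-outcome models: expected
#' outcome events divided by the number of candidate predictor parameters.
#'
#' @param scenario A [sim_scenario()].
#' @return A single number, e.g. 2.5 for n = 100 with 20 parameters at 50%
#'   prevalence.
#' @export
events_per_parameter <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  scenario$n_dev * scenario$event_prop / scenario$n_predictors
}

#' Draw a predictor matrix with a correlated true block
#'
#' Predictors are multivariate normal with mean 0 and unit variance: the
#' first `n_true` columns are pairwise correlated at `rho_true`, the
#' remaining `n_noise` columns are independent.
#'
#' @param n Number of rows (participants).
#' @param n_true,n_noise Sizes of the correlated and independent blocks.
#' @param rho_true Pairwise correlation within the true block.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` by `n_true + n_noise` numeric matrix with columns
#'   `x1 ... xp`.
#' @export
make_predictor_matrix <- function(n, n_true, n_noise, rho_true, seed = NULL) {
  stopifnot(n >= 2, n_true >= 0, n_noise >= 0)
  p <- n_true + n_noise
  sigma <- diag(p)
  if (n_true > 1) {
    sigma[seq_len(n_true), seq_len(n_true)] <- rho_true
    diag(sigma) <- 1
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("correlation matrix implied by rho_true = ", rho_true,
         " is not positive definite", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  colnames(x) <- paste0("x", seq_len(p))
  x
}

new_sim_dataset <- function(df, true_beta, true_intercept, family) {
  out <- tibble::as_tibble(df)
  attr(out, "true_beta") <- true_beta
  attr(out, "true_intercept") <- true_intercept
  attr(out, "family") <- family
  class(out) <- c("sim_dataset", class(out))
  out
}

#' Simulate a binary-outcome development (or validation) dataset
#'
#' Outcomes are Bernoulli draws from a logistic model whose linear predictor
#' is `qlogis(event_prop) + X %*% beta`, with `beta` equal to
#' `effect_size` on the true predictors and 0 on the noise predictors. At
#' the design prevalence of 0.5 the intercept is 0 and the symmetry of the
#' predictors makes the expected prevalence exactly one half; at other
#' values of `event_prop` the achieved prevalence is approximate.
#'
#' @param scenario A [sim_scenario()].
#' @param n Number of rows; defaults to the scenario's development size. Use
#'   `scenario$n_val` to draw a validation set from the same generator.
#' @param effect_size Generating coefficient on the true predictors;
#'   defaults to the scenario's value.
#' @param seed Optional integer seed.
#' @return A tibble with predictor columns `x1 ... xp` and outcome `y`
#'   (0/1), carrying the generating coefficients as attributes (see
#'   [true_coef()]).
#' @examples
#' d <- simulate_binary(sim_scenario(n_dev = 200), seed = 1)
#' mean(d$y) # close to 0.5
#' @export
simulate_binary <- function(scenario, n = scenario$n_dev,
                            effect_size = scenario$effect_size,
                            seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"), effect_size >= 0)
  x <- make_predictor_matrix(n, scenario$n_true, scenario$n_noise,
                             scenario$rho_true, seed = seed)
  beta <- c(rep(effect_size, scenario$n_true),
            rep(0, scenario$n_noise))
  names(beta) <- colnames(x)
  alpha <- stats::qlogis(scenario$event_prop)
  lp <- alpha + drop(x %*% beta)
  y <- stats::rbinom(n, 1L, stats::plogis(lp))
  new_sim_dataset(cbind(as.data.frame(x), y = y), beta, alpha, "binary")
}

#' Simulate a continuous-outcome fixture with a chosen population R-squared
#'
#' Builds a linear-Gaussian dataset whose population R-squared equals
#' `target_r2`: all `p` predictors are independent standard normal with a
#' common slope `b`, and the noise standard deviation is 1, so
#' `R2 = p b^2 / (p b^2 + 1)` and `b = sqrt(target_r2 / ((1 - target_r2) p))`.
#' At large `n` the fitted apparent R-squared approaches `target_r2`. These
#' fixtures emulate the low / medium / high apparent-R-squared regimes
#' (around 0.23, 0.56 and 0.81) of typical continuous-outcome clinical
#' models.
#'
#' @param n Sample size.
#' @param p Number of predictors (all carry signal).
#' @param target_r2 Population proportion of outcome variance explained,
#'   strictly between 0 and 1.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x1 ... xp`, `y` and generating-coefficient
#'   attributes.
#' @examples
#' d <- simulate_continuous_fixture(500, p = 4, target_r2 = 0.81, seed = 1)
#' summary(lm(y ~ ., data = d))$r.squared
#' @export
simulate_continuous_fixture <- function(n, p, target_r2, seed = NULL) {
  stopifnot(n >= 2, p >= 1)
  if (target_r2 <= 0 || target_r2 >= 1) {
    stop("`target_r2` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  b <- sqrt(target_r2 / ((1 - target_r2) * p))
  beta <- rep(b, p)
  names(beta) <- colnames(x)
  y <- drop(x %*% beta) + stats::rnorm(n)
  new_sim_dataset(cbind(as.data.frame(x), y = y), beta, 0, "continuous")
}

#' Generating coefficients of a simulated dataset
#'
#' @param data A dataset from [simulate_binary()] or
#'   [simulate_continuous_fixture()].
#' @return For `true_coef`, the named generating coefficient vector; for
#'   `true_intercept`, the generating intercept; for `dataset_family`,
#'   `"binary"` or `"continuous"`.
#' @export
true_coef <- function(data) attr(data, "true_beta")

#' @rdname true_coef
#' @export
true_intercept <- function(data) attr(data, "true_intercept")

#' @rdname true_coef
#' @export
dataset_family <- function(data) {
  fam <- attr(data, "family")
  if (!is.null(fam)) return(fam)
  y <- data[["y"]]
  if (is.null(y)) stop("dataset has no `y` column", call. = FALSE)
  if (all(y %in% c(0, 1))) "binary" else "continuous"
}

predictor_matrix <- function(data) {
  cols <- setdiff(names(data), "y")
  as.matrix(data[cols])
}

#' Write or read a simulated dataset as CSV with a metadata sidecar
#'
#' The CSV holds the `x1 ... xp, y` columns; a `<path>.json` sidecar records
#' the family, seed (if supplied) and generating coefficients so a
#' round-tripped dataset keeps its ground truth.
#'
#' @param data A simulated dataset tibble.
#' @param path CSV file path.
#' @param seed Seed to record in the sidecar (metadata only).
#' @return `write_sim_csv` returns `path` invisibly; `read_sim_csv` returns
#'   the dataset tibble with attributes restored when the sidecar exists.
#' @export
write_sim_csv <- function(data, path, seed = NULL) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- list(family = dataset_family(data),
               true_intercept = true_intercept(data),
               true_beta = as.list(true_coef(data)),
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_csv
#' @export
read_sim_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    new_sim_dataset(df, unlist(meta$true_beta), meta$true_intercept,
                    meta$family)
  } else {
    new_sim_dataset(df, NULL, NULL, NULL)
  }
}
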