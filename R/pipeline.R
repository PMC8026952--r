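all_methods <- c("mle", "heuristic_shrink", "bootstrap_shrink",
                 "ridge", "lasso", "elastic_net")

method_alpha <- function(method, alpha_mix) {
  switch(method, ridge = 0, lasso = 1, elastic_net = alpha_mix,
         NA_real_)
}

# derive per-replicate seeds from a master seed so replicates are
# individually reproducible and order-independent
spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

develop_one <- function(dev, method, k_folds, n_boot_shrink, n_boot_cv,
                        alpha_mix, ridge_bootstrap_cv, seed) {
  if (method == "mle") {
    fit <- fit_mle(dev)
    return(list(fit = fit, tuning = NA_real_))
  }
  if (method %in% c("heuristic_shrink", "bootstrap_shrink")) {
    base <- fit_mle(dev)
    s <- if (method == "heuristic_shrink") {
      suppressWarnings(heuristic_shrinkage(likelihood_summary(dev, base)))
    } else {
      bootstrap_shrinkage(dev, n_boot = n_boot_shrink, seed = seed)$s_mean
    }
    lab <- if (method == "heuristic_shrink") "heuristic_shrunk"
           else "bootstrap_shrunk"
    return(list(fit = apply_shrinkage(base, s, dev, method = lab),
                tuning = s))
  }
  a <- method_alpha(method, alpha_mix)
  sel <- if (method == "ridge" && ridge_bootstrap_cv) {
    select_lambda_bootstrap_cv(dev, alpha_mix = a, n_boot = n_boot_cv,
                               k_folds = k_folds, seed = seed)
  } else {
    select_lambda_cv(dev, alpha_mix = a, k_folds = k_folds, seed = seed)
  }
  fit <- fit_penalized(dev, lambda = sel$chosen_lambda, alpha_mix = a,
                       method = method)
  list(fit = fit, tuning = sel$chosen_lambda)
}

#' Run one Monte-Carlo scenario across model-development methods
#'
#' For each replicate: generate a development dataset from the scenario,
#' develop a model with every requested method (unpenalized maximum
#' likelihood, heuristic and bootstrap uniform shrinkage, and
#' cross-validation-tuned ridge, lasso and elastic net), generate an
#' independent validation dataset of `scenario$n_val` rows from the same
#' generator, and evaluate each model on it. Per-replicate failures
#' (separation, degenerate cross-validation folds) are recorded with a
#' reason and the run continues.
#'
#' @param scenario A [sim_scenario()].
#' @param methods Subset of
#'   `c("mle", "heuristic_shrink", "bootstrap_shrink", "ridge", "lasso",
#'   "elastic_net")`.
#' @param seed Master seed; every replicate's generator, bootstrap and fold
#'   seeds derive from it, so identical master seeds give identical results
#'   regardless of execution order.
#' @param n_sim Number of replicates; defaults to the scenario's `n_sim`.
#' @param k_folds Folds for cross-validated tuning.
#' @param n_boot_shrink Bootstrap samples for the uniform shrinkage factor.
#' @param n_boot_cv Bootstrap samples for bootstrap cross-validated ridge
#'   tuning (only used when `ridge_bootstrap_cv = TRUE`).
#' @param alpha_mix Elastic-net mixing weight.
#' @param ridge_bootstrap_cv If `TRUE`, tune ridge by bootstrap K-fold
#'   cross-validation instead of plain K-fold.
#' @param shared_validation If `TRUE`, reuse one validation dataset for all
#'   replicates instead of drawing a fresh one per replicate.
#' @param progress Print per-replicate progress to standard error.
#' @return A tibble of class `scenario_results` with one row per replicate
#'   and method: `n_dev`, `replicate`, `method`, `tuning` (chosen lambda or
#'   applied S), `converged`, the four validation metrics, `seed` and
#'   `note` (failure reason, `NA` when successful).
#' @examples
#' sc <- sim_scenario(n_dev = 100, n_sim = 2, n_val = 500)
#' run_scenario(sc, methods = c("mle", "lasso"), seed = 1,
#'              n_boot_shrink = 50)
#' @export
run_scenario <- function(scenario, methods = all_methods, seed = 1,
                         n_sim = scenario$n_sim, k_folds = 5,
                         n_boot_shrink = 500, n_boot_cv = 200,
                         alpha_mix = 0.5, ridge_bootstrap_cv = FALSE,
                         shared_validation = FALSE, progress = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  seeds <- spawn_seeds(seed, 3 * n_sim + 1)
  val_shared <- if (shared_validation) {
    simulate_binary(scenario, n = scenario$n_val,
                    seed = seeds[3 * n_sim + 1])
  }
  rows <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    if (progress) message("replicate ", i, "/", n_sim)
    dev <- simulate_binary(scenario, seed = seeds[3 * i - 2])
    val <- if (shared_validation) val_shared else {
      simulate_binary(scenario, n = scenario$n_val, seed = seeds[3 * i - 1])
    }
    fit_seed <- seeds[3 * i]
    rows[[i]] <- purrr::map_dfr(methods, function(m) {
      res <- tryCatch({
        d <- develop_one(dev, m, k_folds, n_boot_shrink, n_boot_cv,
                         alpha_mix, ridge_bootstrap_cv, fit_seed)
        v <- validate_model(d$fit, val)
        tibble::tibble(method = m, tuning = d$tuning,
                       converged = d$fit$converged,
                       c_index = v$c_index, nagelkerke_r2 = v$nagelkerke_r2,
                       citl = v$citl, cal_slope = v$cal_slope,
                       note = NA_character_)
      }, error = function(e) {
        tibble::tibble(method = m, tuning = NA_real_, converged = FALSE,
                       c_index = NA_real_, nagelkerke_r2 = NA_real_,
                       citl = NA_real_, cal_slope = NA_real_,
                       note = conditionMessage(e))
      })
      dplyr::mutate(res, n_dev = scenario$n_dev, replicate = i,
                    seed = fit_seed, .before = 1)
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scenario_results", class(out))
  out
}

#' Summarize scenario results
#'
#' Groups by development size and method and reports the median and the
#' 2.5th, 25th, 75th and 97.5th percentiles of each validation metric and
#' of the tuning value, plus the failure count. These are the quantities the
#' study's boxplots display: average performance and, above all, its
#' variability across replicate developed models.
#'
#' @param results A `scenario_results` tibble (rows from several scenarios
#'   can be bound together first).
#' @return A tibble with one row per `n_dev` x `method` x quantity.
#' @export
summarize_results <- function(results) {
  if (nrow(results) == 0) stop("no results to summarize", call. = FALSE)
  qs <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) {
      return(tibble::tibble(median = NA_real_, q025 = NA_real_,
                            q25 = NA_real_, q75 = NA_real_,
                            q975 = NA_real_))
    }
    q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    tibble::tibble(median = q[3], q025 = q[1], q25 = q[2], q75 = q[4],
                   q975 = q[5])
  }
  results |>
    tidyr::pivot_longer(c("tuning", "c_index", "nagelkerke_r2", "citl",
                          "cal_slope"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$n_dev, .data$method, .data$quantity) |>
    dplyr::reframe(n_ok = sum(is.finite(.data$value)),
                   n_failed = sum(!is.finite(.data$value)),
                   qs(.data$value)) |>
    dplyr::arrange(.data$n_dev, .data$method, .data$quantity)
}

#' Bootstrap shrinkage across a ladder of subsample sizes
#'
#' Re-creates the subsampling experiment on the uncertainty of the uniform
#' shrinkage factor: for each size in `sizes`, take a random subset of the
#' data (nested by default, so smaller subsets are drawn from larger ones)
#' and run [bootstrap_shrinkage()] on it.
#'
#' @param data Full development dataset.
#' @param sizes Subset sizes, each at least `p + 3`.
#' @param n_boot Bootstrap samples per size.
#' @param seed Master seed.
#' @param nested If `TRUE`, subsets are nested (each smaller subset drawn
#'   from the previous one); if `FALSE`, each is drawn independently from
#'   the full data.
#' @param family `"binary"` or `"continuous"`.
#' @return A tibble of class `shrinkage_curve`: `n`, `s_mean`, `ci_low`,
#'   `ci_high`, `n_failed`.
#' @examples
#' d <- simulate_continuous_fixture(300, p = 4, target_r2 = 0.8, seed = 1)
#' subsampling_shrinkage_curve(d, sizes = c(300, 100, 50), n_boot = 100,
#'                             seed = 2)
#' @export
subsampling_shrinkage_curve <- function(data, sizes, n_boot = 1000,
                                        seed = 1, nested = TRUE,
                                        family = dataset_family(data)) {
  p <- ncol(predictor_matrix(data))
  if (any(sizes > nrow(data))) {
    stop("subset sizes exceed the number of rows (", nrow(data), ")",
         call. = FALSE)
  }
  if (any(sizes <= p + 2)) {
    stop("subset sizes must exceed p + 2 = ", p + 2, call. = FALSE)
  }
  sizes <- sort(unique(sizes), decreasing = TRUE)
  seeds <- spawn_seeds(seed, 2 * length(sizes))
  current <- data
  rows <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    pool <- if (nested) current else data
    set.seed(seeds[2 * k - 1])
    idx <- sample.int(nrow(pool), sizes[k])
    sub <- pool[idx, , drop = FALSE]
    bs <- bootstrap_shrinkage(sub, family = family, n_boot = n_boot,
                              seed = seeds[2 * k])
    rows[[k]] <- tibble::tibble(n = sizes[k], s_mean = bs$s_mean,
                                ci_low = bs$ci_low, ci_high = bs$ci_high,
                                n_failed = bs$n_failed)
    if (nested) current <- sub
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shrinkage_curve", class(out))
  out
}

#' How much do predictions move across a shrinkage interval?
#'
#' Applies the lower and upper bound of a shrinkage-factor interval (for
#' example the ends of its bootstrap 95% confidence interval) to the same
#' fitted model — re-estimating the intercept each time — and reports the
#' absolute per-individual difference in predictions, plus how many
#' individuals move by more than `threshold`. For a Gaussian model the
#' difference has the closed form
#' `(s_high - s_low) * |LP - mean(LP)|` (outcome units, e.g. mmHg); for a
#' logistic model it is on the probability scale.
#'
#' @param data Development data (individuals to predict for).
#' @param fit The unpenalized `cpm_fit` the shrinkage applies to.
#' @param s_low,s_high Lower and upper shrinkage values, `s_low <= s_high`.
#' @param threshold Difference that counts as materially discrepant
#'   (e.g. 10 mmHg for a blood-pressure model, or 0.1 on the probability
#'   scale).
#' @return A tibble of class `pred_diff` with columns `id`, `pred_low`,
#'   `pred_high`, `abs_diff`, `exceeds`; the exceedance count and proportion
#'   are available via [glance.pred_diff()].
#' @export
prediction_difference <- function(data, fit, s_low, s_high,
                                  threshold = 10) {
  stopifnot(inherits(fit, "cpm_fit"))
  if (s_low > s_high) stop("`s_low` must not exceed `s_high`", call. = FALSE)
  type <- if (fit$family == "binary") "response" else "link"
  m_low <- apply_shrinkage(fit, s_low, data, method = "shrunk_low")
  m_high <- apply_shrinkage(fit, s_high, data, method = "shrunk_high")
  pl <- predict(m_low, data, type = type)
  ph <- predict(m_high, data, type = type)
  out <- tibble::tibble(id = seq_along(pl), pred_low = pl, pred_high = ph,
                        abs_diff = abs(ph - pl),
                        exceeds = abs(ph - pl) > threshold)
  attr(out, "threshold") <- threshold
  attr(out, "s_low") <- s_low
  attr(out, "s_high") <- s_high
  class(out) <- c("pred_diff", class(out))
  out
}
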