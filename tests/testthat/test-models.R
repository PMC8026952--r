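test_that("unpenalized fits match closed-form OLS and flag degenerate input", {
  d <- simulate_continuous_fixture(80, p = 5, target_r2 = 0.5, seed = 41)
  fit <- fit_mle(d)
  x <- cbind(1, as.matrix(d[paste0("x", 1:5)]))
  beta_ne <- drop(solve(crossprod(x), crossprod(x, d$y)))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(beta_ne),
               tolerance = 1e-8)

  dc <- d
  dc$y <- 1
  expect_error(fit_mle(dc, family = "binary"), "degenerate")
  expect_error(fit_mle(dc, family = "continuous"), "degenerate")
})

test_that("perfect separation is reported through the convergence flag", {
  d <- tibble::tibble(x1 = c(-(5:1), 1:5), y = rep(c(0, 1), each = 5))
  fit <- suppressWarnings(fit_mle(d, family = "binary"))
  expect_false(fit$converged)
})

test_that("penalized fit at lambda 0 equals maximum likelihood", {
  sc <- sim_scenario(n_dev = 250)
  d <- simulate_binary(sc, seed = 51)
  mle <- fit_mle(d)
  for (a in c(0, 0.5, 1)) {
    pen0 <- fit_penalized(d, lambda = 0, alpha_mix = a)
    expect_lt(max(abs(c(pen0$intercept, pen0$coefficients) -
                        c(mle$intercept, mle$coefficients))), 1e-6)
  }
  expect_error(fit_penalized(d, lambda = -1), "nonnegative")
})

test_that("at and beyond the lasso lambda-max all slopes are zero", {
  d <- simulate_binary(sim_scenario(n_dev = 150), seed = 52)
  grid <- lambda_path(d, alpha_mix = 1)
  expect_true(all(diff(grid) < 0))
  expect_identical(grid, lambda_path(d, alpha_mix = 1))
  at_max <- fit_penalized(d, lambda = grid[1], alpha_mix = 1)
  expect_true(all(at_max$coefficients == 0))
  beyond <- fit_penalized(d, lambda = 2 * grid[1], alpha_mix = 1)
  expect_true(all(beyond$coefficients == 0))
  # intercept of the empty model is the log-odds of the prevalence
  expect_equal(unname(beyond$intercept), qlogis(mean(d$y)), tolerance = 1e-6)
})

test_that("ridge solutions agree with a generic convex optimizer", {
  d <- tiny_binary_fixture(n = 40, p = 3, seed = 53)
  xs <- standardize_pop(as.matrix(d[paste0("x", 1:3)]))
  for (lam in c(0.05, 0.2)) {
    fit <- fit_penalized(d, lambda = lam, alpha_mix = 0, family = "binary")
    opt <- optim(rep(0, 4), penalized_objective, xs = xs, y = d$y,
                 lambda = lam, alpha_mix = 0, family = "binary",
                 method = "BFGS", control = list(reltol = 1e-14, maxit = 1e4))
    # compare on the standardized scale the objective is defined on
    sds <- attr(xs, "scaled:scale")
    b_std <- fit$coefficients * sds
    expect_lt(max(abs(b_std - opt$par[-1])), 1e-4)
    expect_lte(penalized_objective(c(fit$intercept +
                                       sum(fit$coefficients *
                                             attr(xs, "scaled:center")),
                                     b_std), xs, d$y, lam, 0, "binary"),
               opt$value + 1e-8)
  }
})

test_that("no coordinate perturbation improves a converged penalized objective", {
  d <- tiny_binary_fixture(n = 60, p = 4, seed = 54)
  xs <- standardize_pop(as.matrix(d[paste0("x", 1:4)]))
  sds <- attr(xs, "scaled:scale")
  ctr <- attr(xs, "scaled:center")
  for (a in c(0, 0.5, 1)) {
    fit <- fit_penalized(d, lambda = 0.08, alpha_mix = a, family = "binary")
    par <- c(fit$intercept + sum(fit$coefficients * ctr),
             fit$coefficients * sds)
    f0 <- penalized_objective(par, xs, d$y, 0.08, a, "binary")
    for (j in seq_along(par)) {
      for (eps in c(-1e-4, 1e-4)) {
        pj <- par
        pj[j] <- pj[j] + eps
        expect_gte(penalized_objective(pj, xs, d$y, 0.08, a, "binary"),
                   f0 - 1e-9)
      }
    }
  }
})

test_that("ridge coefficient norms shrink as lambda grows", {
  d <- simulate_binary(sim_scenario(n_dev = 200), seed = 55)
  grid <- lambda_path(d, alpha_mix = 0, n_lambda = 25)
  norms <- vapply(grid, function(l) {
    sqrt(sum(fit_penalized(d, l, alpha_mix = 0)$coefficients^2))
  }, numeric(1))
  # grid is descending, so norms must be nondecreasing along it
  expect_true(all(diff(norms) > -1e-8))
  # lasso endpoint sparsity: everything zero at lambda_max, nothing at 0
  lmax <- lambda_path(d, alpha_mix = 1)[1]
  expect_equal(sum(fit_penalized(d, lmax, 1)$coefficients != 0), 0)
  expect_equal(sum(fit_penalized(d, 0, 1)$coefficients != 0), 20)
})

test_that("leave-one-out tuning matches an exhaustive oracle", {
  d <- tiny_binary_fixture(n = 20, p = 2, seed = 56)
  grid <- lambda_path(d, alpha_mix = 1, n_lambda = 12)
  sel <- select_lambda_cv(d, alpha_mix = 1, k_folds = 20, grid = grid,
                          seed = 57)
  # oracle: per-observation held-out deviance, averaged over the n folds
  x <- as.matrix(d[paste0("x", 1:2)])
  dev <- matrix(NA_real_, 20, length(grid))
  for (i in 1:20) {
    fit <- glmnet::glmnet(x[-i, ], d$y[-i], family = "binomial", alpha = 1,
                          lambda = grid, standardize = TRUE, thresh = 1e-10)
    p <- drop(plogis(predict(fit, x[i, , drop = FALSE], s = grid,
                             type = "link")))
    dev[i, ] <- -2 * (d$y[i] * log(p) + (1 - d$y[i]) * log(1 - p))
  }
  oracle_curve <- colMeans(dev)
  expect_equal(sel$cv_deviance, oracle_curve, tolerance = 1e-6)
  expect_equal(sel$chosen_lambda, grid[which.min(oracle_curve)])
})

test_that("cross-validation selection is stratified, seeded and tie-broken upward", {
  d <- simulate_binary(sim_scenario(n_dev = 100), seed = 58)
  a <- select_lambda_cv(d, alpha_mix = 1, seed = 59)
  b <- select_lambda_cv(d, alpha_mix = 1, seed = 59)
  expect_identical(a$cv_deviance, b$cv_deviance)
  expect_true(a$chosen_lambda %in% a$lambda_grid)
  # chosen lambda is the largest minimizer of the deviance curve
  expect_equal(a$chosen_lambda,
               max(a$lambda_grid[a$cv_deviance == min(a$cv_deviance)]))
})

test_that("pure-noise data drive the chosen lambda toward the grid maximum", {
  sc <- sim_scenario(n_dev = 200, effect_size = 0)
  hits <- vapply(1:30, function(i) {
    d <- simulate_binary(sc, seed = 900 + i)
    sel <- select_lambda_cv(d, alpha_mix = 1, n_lambda = 50, seed = 950 + i)
    # at or near the all-zero end of the grid (top decile)
    sel$chosen_lambda >= sel$lambda_grid[5]
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("bootstrap cross-validation reduces tuning variability", {
  # B = 1 collapses to plain CV on a single resample
  d <- tiny_binary_fixture(n = 30, p = 2, seed = 60)
  one <- select_lambda_bootstrap_cv(d, alpha_mix = 0, n_boot = 1, seed = 61)
  expect_length(one$per_boot_lambdas, 1)
  expect_equal(one$chosen_lambda, one$per_boot_lambdas[1])
  # odd B: the median is an observed per-bootstrap lambda
  odd <- select_lambda_bootstrap_cv(d, alpha_mix = 0, n_boot = 5, seed = 62)
  expect_true(odd$chosen_lambda %in% odd$per_boot_lambdas)

  # across outer replicates at n = 100, bootstrap-CV lambdas vary less
  sc <- sim_scenario(n_dev = 100)
  lam_cv <- lam_bt <- numeric(12)
  for (i in 1:12) {
    dd <- simulate_binary(sc, seed = 1200 + i)
    lam_cv[i] <- select_lambda_cv(dd, alpha_mix = 0, n_lambda = 60,
                                  seed = 1250 + i)$chosen_lambda
    lam_bt[i] <- select_lambda_bootstrap_cv(dd, alpha_mix = 0, n_boot = 20,
                                            n_lambda = 60,
                                            seed = 1300 + i)$chosen_lambda
  }
  expect_lt(var(lam_bt), var(lam_cv))
})

test_that("5-fold and 10-fold cross-validation choose similar lambdas at n = 500", {
  sc <- sim_scenario(n_dev = 500)
  l5 <- l10 <- numeric(12)
  for (i in 1:12) {
    d <- simulate_binary(sc, seed = 1400 + i)
    l5[i] <- select_lambda_cv(d, alpha_mix = 1, k_folds = 5,
                              seed = 1450 + i)$chosen_lambda
    l10[i] <- select_lambda_cv(d, alpha_mix = 1, k_folds = 10,
                               seed = 1500 + i)$chosen_lambda
  }
  # trend-level agreement: median difference small relative to the IQR
  expect_lt(abs(median(l5) - median(l10)),
            max(IQR(l5), IQR(l10), 1e-8))
})

test_that("fitted models round-trip through their JSON records", {
  d <- simulate_binary(sim_scenario(n_dev = 120), seed = 63)
  fit <- fit_penalized(d, lambda = 0.05, alpha_mix = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$method, fit$method)
  expect_equal(predict(back, d), predict(fit, d))
})

test_that("an effect-size override changes only the generating coefficients", {
  sc <- sim_scenario(n_dev = 50)
  d0 <- simulate_binary(sc, effect_size = 0, seed = 64)
  expect_true(all(true_coef(d0) == 0))
  d1 <- simulate_binary(sc, effect_size = 0.9, seed = 64)
  expect_equal(unname(true_coef(d1)[1:5]), rep(0.9, 5))
  expect_equal(as.matrix(d0[paste0("x", 1:20)]),
               as.matrix(d1[paste0("x", 1:20)]))
})
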