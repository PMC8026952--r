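# Independent brute-force oracles used across test files.

# O(n^2) pairwise concordance: ties in risk count one half
c_index_oracle <- function(y, risk) {
  ev <- which(y == 1)
  ne <- which(y == 0)
  tot <- 0
  for (i in ev) {
    for (j in ne) {
      tot <- tot + if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
    }
  }
  tot / (length(ev) * length(ne))
}

# naive calibration metrics through stats::glm formulas
cal_slope_oracle <- function(y, lp) {
  unname(coef(glm(y ~ lp, family = binomial()))[2])
}
citl_oracle <- function(y, lp) {
  unname(coef(glm(y ~ 1 + offset(lp), family = binomial()))[1])
}

# elastic-net objective on the standardized scale (glmnet convention):
# mean negative log-likelihood plus penalty, intercept unpenalized
penalized_objective <- function(par, xs, y, lambda, alpha_mix, family) {
  a <- par[1]
  b <- par[-1]
  lp <- a + drop(xs %*% b)
  n <- length(y)
  nll <- if (family == "binary") {
    mean(log(1 + exp(lp)) - y * lp)
  } else {
    mean((y - lp)^2) / 2
  }
  nll + lambda * (alpha_mix * sum(abs(b)) + (1 - alpha_mix) / 2 * sum(b^2))
}

# standardize columns with population (1/n) variance, as the penalty does
standardize_pop <- function(x) {
  scale(x, center = TRUE,
        scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
}

tiny_binary_fixture <- function(n = 20, p = 2, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  lp <- 0.8 * x[, 1] - 0.5 * x[, 2]
  y <- rbinom(n, 1, plogis(lp))
  # ensure both classes well represented for K = n cross-validation
  if (sum(y) < 3) y[1:3] <- 1
  if (sum(1 - y) < 3) y[(n - 2):n] <- 0
  tibble::as_tibble(cbind(as.data.frame(x), y = y))
}
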