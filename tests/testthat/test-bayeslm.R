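simple_spec <- function(response = "y", main = c("x", "plot_area")) {
  list(response = response, main = main, interactions = character(0),
       label = paste(main, collapse = " + "))
}

test_that("a known slope is recovered on the raw scale", {
  set.seed(1)
  n <- 100
  d <- data.frame(x = rnorm(n), plot_area = runif(n))
  d$y <- 2 * d$x + rnorm(n, 0, 0.1)
  fit <- fit_bayes_lm(simple_spec(), d, seed = 2)
  slope <- fit$coef$median_raw[fit$coef$term == "x"]
  expect_gt(slope, 1.9)
  expect_lt(slope, 2.1)
  expect_true(fit$converged)
  expect_gt(fit$r2_adj, 0.95)
})

test_that("the intercept-only model recovers the sample mean", {
  set.seed(2)
  d <- data.frame(y = rnorm(40, 5), plot_area = runif(40))
  fit <- fit_bayes_lm(simple_spec(main = "plot_area"), d, seed = 3)
  sem <- sd(d$y) / sqrt(40)
  expect_lt(abs(fit$coef$median[1] - mean(d$y)), 2 * sem)
})

test_that("a pure-noise covariate lands mostly inside the ROPE", {
  set.seed(3)
  d <- data.frame(x = rnorm(100), plot_area = runif(100))
  d$y <- rnorm(100)
  fit <- fit_bayes_lm(simple_spec(), d, seed = 4)
  expect_gt(fit$coef$rope[fit$coef$term == "x"], 0.5)
})

test_that("pre-standardized and raw predictors yield identical posteriors", {
  set.seed(4)
  n <- 30
  d <- data.frame(x = rnorm(n, 50, 9), plot_area = runif(n, 0.5, 1))
  d$y <- 0.02 * d$x + rnorm(n, 0, 0.3)
  dstd <- d
  dstd$x <- as.numeric(scale(d$x))
  dstd$plot_area <- as.numeric(scale(d$plot_area))
  f1 <- fit_bayes_lm(simple_spec(), d, iter = 2000, seed = 5)
  f2 <- fit_bayes_lm(simple_spec(), dstd, iter = 2000, seed = 5)
  # identical posteriors up to Monte Carlo error (floating-point detail of
  # the internal standardization can permute the RNG stream)
  mc_se <- apply(f1$draws, 2, sd) / sqrt(500)
  expect_true(all(abs(f1$coef$median - f2$coef$median) < 4 * mc_se + 1e-12))
})

test_that("small-sample fits warn about overparameterization", {
  set.seed(5)
  d <- data.frame(x = rnorm(4), plot_area = runif(4), y = rnorm(4))
  expect_warning(fit_bayes_lm(simple_spec(), d, iter = 400, seed = 6),
                 class = "overparameterized")
})

test_that("looic is exactly -2 elpd and mismatched fits are rejected", {
  set.seed(6)
  n <- 15
  d <- data.frame(x = rnorm(n), plot_area = runif(n))
  d$y <- d$x + rnorm(n, 0, 0.5)
  fit <- fit_bayes_lm(simple_spec(), d, iter = 800, seed = 7)
  loo <- loo_elpd(fit, d, method = "exact", iter = 600)
  expect_equal(loo$looic, -2 * loo$elpd, tolerance = 1e-9)
  expect_length(loo$elpd_i, n)

  d2 <- d
  d2$y <- d2$y + 1
  fit2 <- fit_bayes_lm(simple_spec(), d2, iter = 800, seed = 7)
  expect_error(loo_compare(list(fit, fit2), d), class = "invalid_comparison")
})

test_that("truncated-importance-sampling LOO tracks exact refits on a small model", {
  set.seed(7)
  n <- 21
  d <- data.frame(x = rnorm(n), plot_area = runif(n))
  d$y <- 0.8 * d$x + rnorm(n, 0, 0.5)
  fit <- fit_bayes_lm(simple_spec(), d, seed = 8)
  exact <- loo_elpd(fit, d, method = "exact")
  tis <- loo_elpd(fit, d, method = "tis")
  expect_lt(abs(exact$elpd - tis$elpd), 1)
  expect_lt(max(abs(exact$elpd_i - tis$elpd_i)), 0.5)
})

test_that("exact LOO matches a direct numerical-integration oracle", {
  set.seed(8)
  n <- 12
  d <- data.frame(x = rnorm(n), plot_area = runif(n))
  d$y <- 0.5 * d$x + rnorm(n, 0, 0.4)
  spec <- simple_spec()
  fit <- fit_bayes_lm(spec, d, iter = 4000, seed = 9)
  loo <- loo_elpd(fit, d, method = "exact", iter = 4000)

  # oracle: integrate the coefficients analytically per sigma (Gaussian
  # algebra) and sigma by quadrature on a dense grid -- no MCMC involved
  oracle_lppd <- function(i) {
    train <- d[-i, , drop = FALSE]
    des <- facetdiv:::build_design(spec, train)
    xt <- des$x
    yt <- train$y
    v0 <- diag(c(100, 6.25, 6.25))
    rate <- 1 / sd(yt)
    sig_grid <- seq(1e-3, 6 * sd(yt), length.out = 2000)
    xi <- drop(facetdiv:::build_design(spec, d[i, , drop = FALSE],
                                       center = des$center,
                                       scale = des$scale)$x)
    log_w <- vapply(sig_grid, function(s) {
      cv <- xt %*% v0 %*% t(xt) + diag(s^2, nrow(xt))
      mvtnorm_ll <- -0.5 * (determinant(cv)$modulus +
                              drop(yt %*% solve(cv, yt)) +
                              nrow(xt) * log(2 * pi))
      mvtnorm_ll + stats::dexp(s, rate, log = TRUE)
    }, numeric(1))
    w <- exp(log_w - max(log_w))
    pred <- vapply(sig_grid, function(s) {
      prec <- crossprod(xt) / s^2 + solve(v0)
      sb <- solve(prec)
      mb <- sb %*% crossprod(xt, yt) / s^2
      stats::dnorm(d$y[i], drop(xi %*% mb),
                   sqrt(drop(xi %*% sb %*% xi) + s^2))
    }, numeric(1))
    log(sum(w * pred) / sum(w))
  }
  oracle <- vapply(seq_len(n), oracle_lppd, numeric(1))
  expect_lt(max(abs(loo$elpd_i - oracle)), 0.05)
})

test_that("ROPE proportions respect containment geometry", {
  set.seed(9)
  expect_equal(rope(rnorm(1000, 10, 0.1), rope_range = c(-0.1, 0.1)), 0)
  expect_equal(rope(rnorm(1000, 0, 0.001), rope_range = c(-0.1, 0.1)), 1)
  mid <- rope(rnorm(1e5, 0.1, 0.1), rope_range = c(-0.1, 0.1))
  expect_gt(mid, 0.2)
  expect_lt(mid, 0.8)
  expect_error(rope(rnorm(1000), rope_range = c(1, -1)),
               class = "invalid_argument")
})
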