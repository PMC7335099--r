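# Build the (standardized) design matrix for a model_spec.  Predictors are
# centred and scaled using `center`/`scale` statistics (computed from
# `data` when not supplied, e.g. from a training fold during
# cross-validation); interaction columns are products of the standardized
# main-effect columns.
build_design <- function(spec, data, center = NULL, scale = NULL) {
  vars <- unique(c(spec$main, unlist(strsplit(spec$interactions, ":", fixed = TRUE))))
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop_facetdiv(paste0("data lacks driver column(s): ",
                         paste(missing, collapse = ", ")), "invalid_argument")
  raw <- as.matrix(data[, vars, drop = FALSE])
  if (is.null(center)) center <- colMeans(raw)
  if (is.null(scale)) {
    scale <- apply(raw, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  std <- sweep(sweep(raw, 2L, center[vars]), 2L, scale[vars], "/")
  x <- std[, spec$main, drop = FALSE]
  for (term in spec$interactions) {
    pair <- strsplit(term, ":", fixed = TRUE)[[1L]]
    x <- cbind(x, std[, pair[1L]] * std[, pair[2L]])
    colnames(x)[ncol(x)] <- term
  }
  list(x = cbind(`(Intercept)` = 1, x), center = center, scale = scale)
}

#' Fit a Bayesian Gaussian linear driver model
#'
#' Gaussian-likelihood linear regression with diffuse normal priors:
#' `N(0, 2.5)` on slope coefficients, `N(0, 10)` on the intercept, and an
#' exponential prior with mean `sd(y)` on the residual scale.  All
#' predictors are centred and scaled internally before fitting (so reported
#' coefficients are on the standardized-predictor scale); interaction terms
#' are products of standardized main effects.  Sampling alternates a
#' conjugate multivariate-normal Gibbs draw of the coefficients with a slice
#' sampling step on `log(sigma)`.
#'
#' @param spec a `model_spec` from [enumerate_models()], or a list with
#'   `response`, `main`, `interactions`.
#' @param data data.frame with the response and all driver columns (one row
#'   per plot).
#' @param chains,iter,warmup,seed MCMC settings (defaults 3 chains of 2000
#'   iterations, half warmup).
#' @param coef_sd,intercept_sd prior standard deviations.
#' @return object of class `bayes_lm`: `coef` table (median, raw-scale
#'   median, HDIs at 50/89/95%, ROPE, Rhat per term), `draws` (kept draws,
#'   all chains stacked), `sigma` draws, `r2_adj`, `converged`, plus the
#'   spec and standardization statistics needed for prediction.
#' @export
fit_bayes_lm <- function(spec, data, chains = 3L, iter = 2000L,
                         warmup = iter %/% 2L, seed = 1L,
                         coef_sd = 2.5, intercept_sd = 10) {
  y <- data[[spec$response]]
  if (is.null(y))
    stop_facetdiv(sprintf("no response column '%s'", spec$response),
                  "invalid_argument")
  des <- build_design(spec, data)
  x <- des$x
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 2L)
    warn_facetdiv(sprintf("n = %d is small for %d terms; posterior relies on priors",
                          n, p - 1L), "overparameterized")
  prior_sd <- c(intercept_sd, rep(coef_sd, p - 1L))
  sigma_rate <- 1 / max(stats::sd(y), .Machine$double.eps)
  keep <- iter - warmup
  xtx <- crossprod(x)
  xty <- drop(crossprod(x, y))
  yty <- sum(y^2)
  # pre-diagonalise likelihood and prior quadratic forms: with
  # W = P0^{-1/2} Q (Q from the eigendecomposition of the prior-whitened
  # X'X), beta = W gamma has prior precision I and likelihood precision
  # diag(lambda)/sigma^2, so every Gibbs update is O(p) vector work
  a <- xtx * tcrossprod(prior_sd)
  ea <- eigen((a + t(a)) / 2, symmetric = TRUE)
  lambda <- pmax(ea$values, 0)
  w_mat <- prior_sd * ea$vectors
  wty <- drop(crossprod(w_mat, xty))            # W' X'y
  set.seed(stage_seed(seed, paste0("lm:", spec$label %||% "model")))
  chain_seeds <- sample.int(2147483000, chains)
  gamma_draws <- matrix(NA_real_, keep * chains, p)
  sigma_draws <- numeric(keep * chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    sig <- stats::sd(y) * stats::runif(1, 0.5, 2)
    for (it in seq_len(iter)) {
      post_prec <- lambda / sig^2 + 1
      gam <- wty / sig^2 / post_prec +
        stats::rnorm(p) / sqrt(post_prec)
      ss <- max(yty - 2 * sum(gam * wty) + sum(gam^2 * lambda), 0)
      log_post_sigma <- function(ls) {
        s <- exp(ls)
        -n * ls - ss / (2 * s^2) - sigma_rate * s + ls
      }
      ls <- slice_sample1(log_post_sigma, log(sig), w = 0.5)
      sig <- exp(ls)
      if (it > warmup) {
        row <- (ch - 1L) * keep + (it - warmup)
        gamma_draws[row, ] <- gam
        sigma_draws[row] <- sig
      }
    }
  }
  beta_draws <- gamma_draws %*% t(w_mat)
  colnames(beta_draws) <- colnames(x)
  rh <- vapply(seq_len(p), function(j)
    rhat(matrix(beta_draws[, j], nrow = keep)), numeric(1L))
  rope_range <- 0.1 * stats::sd(y)
  med <- apply(beta_draws, 2L, stats::median)
  # raw-predictor-scale slopes for interpretation (intercept left as fitted)
  raw_scale <- c(1, vapply(colnames(x)[-1L], function(term) {
    pair <- strsplit(term, ":", fixed = TRUE)[[1L]]
    prod(des$scale[pair])
  }, numeric(1L)))
  coef_tab <- data.frame(
    term = colnames(x),
    median = med,
    median_raw = med / raw_scale,
    hdi50_l = NA_real_, hdi50_h = NA_real_,
    hdi89_l = NA_real_, hdi89_h = NA_real_,
    hdi95_l = NA_real_, hdi95_h = NA_real_,
    rope = NA_real_, rhat = rh, row.names = NULL)
  for (j in seq_len(p)) {
    coef_tab[j, c("hdi50_l", "hdi50_h")] <- hdi(beta_draws[, j], 0.50)
    coef_tab[j, c("hdi89_l", "hdi89_h")] <- hdi(beta_draws[, j], 0.89)
    coef_tab[j, c("hdi95_l", "hdi95_h")] <- hdi(beta_draws[, j], 0.95)
    coef_tab$rope[j] <- rope(beta_draws[, j], rope_range = c(-rope_range, rope_range))
  }
  fitted_med <- drop(x %*% med)
  r2 <- 1 - sum((y - fitted_med)^2) / sum((y - mean(y))^2)
  r2_adj <- 1 - (1 - r2) * (n - 1) / max(n - p, 1L)
  structure(list(
    spec = spec, coef = coef_tab, draws = beta_draws, sigma = sigma_draws,
    keep = keep, chains = chains, r2_adj = r2_adj,
    converged = all(rh <= 1.05), center = des$center, scale = des$scale,
    y = y, n = n,
    mcmc = list(chains = chains, iter = iter, warmup = warmup, seed = seed)
  ), class = "bayes_lm")
}

#' @export
print.bayes_lm <- function(x, ...) {
  cat(sprintf("<bayes_lm> %s ~ %s  (n = %d, R2_adj = %.2f%s)\n",
              x$spec$response, x$spec$label, x$n, x$r2_adj,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$coef[, c("term", "median", "hdi89_l", "hdi89_h", "rope", "rhat")],
        digits = 3)
  invisible(x)
}

# Log pointwise predictive density of observation(s) under a fitted model's
# draws: log mean_s N(y | x beta_s, sigma_s).
lppd_point <- function(fit, xrow, y) {
  mu <- drop(fit$draws %*% xrow)
  ll <- stats::dnorm(y, mu, fit$sigma, log = TRUE)
  m <- max(ll)
  m + log(mean(exp(ll - m)))
}

#' Leave-one-out expected log predictive density of a driver model
#'
#' `method = "exact"` (the reference) refits the model once per held-out
#' plot, standardizing predictors on the training fold only, and evaluates
#' the log posterior-predictive density of the held-out observation.
#' `method = "tis"` approximates the same quantity from the full fit by
#' truncated importance sampling (raw weights truncated at
#' `mean(w) * sqrt(S)`), avoiding the n refits.
#'
#' @param fit a `bayes_lm` fit (fitted on the full data).
#' @param data the data the model was fitted on.
#' @param method `"exact"` or `"tis"`.
#' @param ... for `"exact"`, MCMC settings forwarded to [fit_bayes_lm()]
#'   (defaults to the settings of `fit`).
#' @return list with `elpd`, `looic` (= -2 elpd), `elpd_i`, `se` (standard
#'   error of elpd) and `method`.
#' @export
loo_elpd <- function(fit, data, method = c("exact", "tis"), ...) {
  method <- match.arg(method)
  y <- data[[fit$spec$response]]
  n <- length(y)
  elpd_i <- numeric(n)
  if (method == "exact") {
    args <- list(...)
    mcmc <- utils::modifyList(fit$mcmc, args)
    for (i in seq_len(n)) {
      train <- data[-i, , drop = FALSE]
      refit <- fit_bayes_lm(fit$spec, train, chains = mcmc$chains,
                            iter = mcmc$iter, warmup = mcmc$warmup,
                            seed = (as.numeric(mcmc$seed) + 977 * i) %% 2147483587)
      des_i <- build_design(fit$spec, data[i, , drop = FALSE],
                            center = refit$center, scale = refit$scale)
      elpd_i[i] <- lppd_point(refit, drop(des_i$x), y[i])
    }
  } else {
    des <- build_design(fit$spec, data, center = fit$center, scale = fit$scale)
    s <- length(fit$sigma)
    for (i in seq_len(n)) {
      mu <- drop(fit$draws %*% des$x[i, ])
      ll <- stats::dnorm(y[i], mu, fit$sigma, log = TRUE)
      r <- exp(-ll - max(-ll))            # raw weights 1/p, stabilised
      w <- pmin(r, mean(r) * sqrt(s))
      elpd_i[i] <- log(sum(w * exp(ll - max(ll))) / sum(w)) + max(ll)
    }
  }
  elpd <- sum(elpd_i)
  list(elpd = elpd, looic = -2 * elpd, elpd_i = elpd_i,
       se = sqrt(n * stats::var(elpd_i)), method = method)
}

#' Rank fitted driver models by leave-one-out cross-validation
#'
#' Computes the LOO expected log predictive density for each fit and ranks
#' models by ascending LOOIC (`looic = -2 * elpd`; lower is better).  All
#' fits must share the same response vector; fits flagged as non-converged
#' are excluded from ranking with a warning.
#'
#' @param fits list of `bayes_lm` fits on identical data.
#' @param data the shared data.frame.
#' @inheritParams loo_elpd
#' @return data.frame ranked by `looic`: `label`, `elpd`, `looic`, `se`,
#'   `elpd_diff` (against the best model), `r2_adj`, `converged`.
#' @export
loo_compare <- function(fits, data, method = c("exact", "tis"), ...) {
  method <- match.arg(method)
  ys <- lapply(fits, function(f) f$y)
  if (length(unique(vapply(ys, function(v) paste(signif(v, 12), collapse = ","),
                           character(1L)))) != 1L)
    stop_facetdiv("fits were not made on identical response data",
                  "invalid_comparison")
  bad <- !vapply(fits, `[[`, logical(1L), "converged")
  if (any(bad))
    warn_facetdiv(sprintf("%d fit(s) flagged non-converged; excluded from ranking",
                          sum(bad)), "nonconverged_fit")
  loos <- lapply(fits, loo_elpd, data = data, method = method, ...)
  out <- data.frame(
    label = vapply(fits, function(f) f$spec$label, character(1L)),
    elpd = vapply(loos, `[[`, numeric(1L), "elpd"),
    looic = vapply(loos, `[[`, numeric(1L), "looic"),
    se = vapply(loos, `[[`, numeric(1L), "se"),
    r2_adj = vapply(fits, `[[`, numeric(1L), "r2_adj"),
    converged = !bad)
  out <- out[order(!out$converged, out$looic), , drop = FALSE]
  out$elpd_diff <- out$elpd - max(out$elpd[out$converged])
  rownames(out) <- NULL
  out
}

#' Region of practical equivalence (ROPE) of a coefficient
#'
#' Fraction of the 89% highest density interval of a coefficient's
#' posterior lying inside a "practically zero" band.  Values near 0
#' indicate a clearly non-negligible effect.
#'
#' @param draws numeric vector of posterior draws.
#' @param hdi_mass mass of the HDI examined (default 0.89).
#' @param rope_range band `c(lower, upper)` considered practically
#'   equivalent to zero.
#' @return proportion in `[0, 1]`.
#' @export
rope <- function(draws, hdi_mass = 0.89, rope_range) {
  if (length(rope_range) != 2L || rope_range[1L] > rope_range[2L])
    stop_facetdiv("rope_range must be c(lower, upper)", "invalid_argument")
  h <- hdi(draws, hdi_mass)
  inside <- draws >= h[1L] & draws <= h[2L]
  if (!any(inside)) return(0)
  mean(draws[inside] >= rope_range[1L] & draws[inside] <= rope_range[2L])
}
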