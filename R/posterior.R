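#' Highest density interval of a sample of draws
#'
#' Shortest contiguous interval containing a given fraction of the empirical
#' distribution, computed by the sliding-window method on sorted draws.
#'
#' @param draws numeric vector of posterior draws (at least 100 for a stable
#'   interval; fewer are rejected).
#' @param mass fraction of posterior mass the interval must contain,
#'   in (0, 1).  Commonly 0.50, 0.89 or 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hdi(rnorm(1e4), 0.95)
#' @export
hdi <- function(draws, mass = 0.89) {
  assert_scalar_number(mass, "mass")
  if (mass <= 0 || mass >= 1)
    stop_facetdiv("`mass` must be strictly between 0 and 1", "invalid_argument")
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L)
    stop_facetdiv("hdi() needs at least 100 draws", "invalid_argument")
  x <- sort(draws)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Probability of direction
#'
#' Percentage of posterior mass on the dominant side of zero: always in
#' \[50, 100\].  A value near 50 means the sign of the effect is undecided;
#' near 100 means the posterior is almost entirely on one side.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @return percentage in \[50, 100\].
#' @export
prob_direction <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L)
    stop_facetdiv("prob_direction() needs at least 100 draws", "invalid_argument")
  100 * max(sum(draws < 0), sum(draws > 0)) / length(draws)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Classic Gelman-Rubin statistic computed after splitting each chain in
#' half, so within-chain drift inflates the statistic too.  Values near 1
#' indicate the chains mix over a common distribution.
#'
#' @param chains a numeric matrix with one column per chain (iterations in
#'   rows), or a list of equal-length numeric vectors.
#' @return the split-Rhat statistic.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  if (!is.matrix(chains) || ncol(chains) < 2L)
    stop_facetdiv("rhat() needs at least 2 chains", "invalid_argument")
  if (nrow(chains) < 4L)
    stop_facetdiv("rhat() needs at least 4 draws per chain", "invalid_argument")
  n <- nrow(chains) %/% 2L
  split <- cbind(chains[seq_len(n), , drop = FALSE],
                 chains[(nrow(chains) - n + 1L):nrow(chains), , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2L, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# One-dimensional slice sampler (stepping-out and shrinkage; Neal 2003).
# logf: log target density; x0: current value; w: step size;
# lower/upper: hard support bounds.
slice_sample1 <- function(logf, x0, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  ly <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1)
  l <- x0 - w * u
  r <- l + w
  steps <- 0L
  while (l > lower && logf(l) > ly && steps < max_steps) {
    l <- l - w; steps <- steps + 1L
  }
  steps <- 0L
  while (r < upper && logf(r) > ly && steps < max_steps) {
    r <- r + w; steps <- steps + 1L
  }
  l <- max(l, lower)
  r <- min(r, upper)
  repeat {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= ly) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
    if (r - l < 1e-12) return(x0)
  }
}
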