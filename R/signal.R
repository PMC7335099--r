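#' Blomberg's K phylogenetic signal statistic
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetically corrected mean (`MSE0`) to the GLS mean squared error
#' under the tree's variance-covariance structure (`MSE`), scaled by the
#' expectation of that ratio under Brownian motion.  K is near 1 when trait
#' variation accumulates along the branches (Brownian motion) and near 0
#' when trait values are independent of the tree.
#'
#' @param trait named numeric vector of tip values (names = tip labels), or
#'   a matrix with one column per trait (rownames = tip labels) for
#'   vectorised evaluation over many traits on the same tree.
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return a single K value, or a vector of K values for a trait matrix.
#' @export
blomberg_k <- function(trait, tree) {
  prep <- k_prepare(tree)
  k_statistic(trait, prep)
}

# Precompute the tree-dependent pieces of K so repeated evaluation (many
# traits, permutations) costs one matrix-vector product per trait.
k_prepare <- function(tree) {
  vcv <- ape::vcv.phylo(tree)
  cinv <- solve(vcv)
  ones <- rep(1, nrow(vcv))
  denom_bm <- (sum(diag(vcv)) - nrow(vcv) / sum(cinv)) / (nrow(vcv) - 1)
  list(tips = rownames(vcv), cinv = cinv, csum = sum(cinv),
       crow = colSums(cinv), expected_ratio = denom_bm, n = nrow(vcv))
}

k_statistic <- function(trait, prep) {
  x <- as.matrix(trait)
  if (is.null(rownames(x)))
    stop_facetdiv("trait values must be named by tip label", "invalid_argument")
  bad <- setdiff(prep$tips, rownames(x))
  if (length(bad))
    stop_facetdiv(paste0("trait missing for tips: ", paste(bad, collapse = ", ")),
                  "missing_tip")
  x <- x[prep$tips, , drop = FALSE]
  if (any(apply(x, 2L, stats::var) == 0))
    stop_facetdiv("trait has zero variance", "degenerate_trait")
  n <- prep$n
  ahat <- drop(prep$crow %*% x) / prep$csum          # phylogenetic mean(s)
  dev <- sweep(x, 2L, ahat)
  mse0 <- colSums(dev^2) / (n - 1)
  mse <- colSums(dev * (prep$cinv %*% dev)) / (n - 1)
  unname((mse0 / mse) / prep$expected_ratio)
}

#' Permutation significance of Blomberg's K
#'
#' Randomises trait values across the tips `n_perm` times and reports
#' `p = (1 + #(K_perm >= K_obs)) / (1 + n_perm)`, the standard
#' finite-permutation estimator (never exactly zero).
#'
#' @inheritParams blomberg_k
#' @param trait named numeric vector of tip values.
#' @param n_perm number of tip randomisations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `k` (observed statistic) and `p_value`.
#' @export
k_significance <- function(trait, tree, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L)
    stop_facetdiv("n_perm must be >= 99", "invalid_argument")
  prep <- k_prepare(tree)
  k_obs <- k_statistic(trait, prep)
  x <- as.numeric(trait[prep$tips])
  set.seed(as.integer(seed %% 2147483647))
  perms <- replicate(n_perm, sample(x))
  rownames(perms) <- prep$tips
  k_null <- k_statistic(perms, prep)
  p <- (1 + sum(k_null >= k_obs)) / (1 + n_perm)
  list(k = k_obs, p_value = p)
}
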