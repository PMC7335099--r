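#' Patristic distance matrix for a species subset
#'
#' Tip-to-tip path lengths (sums of branch lengths) for the requested tips.
#' Warns, but does not fail, if the tree departs from ultrametry by more
#' than 1e-6 relative to its height.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param species character vector of tip labels; defaults to all tips.
#' @return symmetric matrix with zero diagonal, dimnames = species.
#' @export
patristic_matrix <- function(tree, species = tree$tip.label) {
  species <- as.character(species)
  bad <- setdiff(species, tree$tip.label)
  if (length(bad))
    stop_facetdiv(paste0("species not in tree: ", paste(bad, collapse = ", ")),
                  "missing_tip")
  check_ultrametric(tree)
  d <- ape::cophenetic.phylo(tree)
  d[species, species, drop = FALSE]
}

check_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h > 0 && (max(depths) - min(depths)) / h > tol)
    warn_facetdiv("tree is not ultrametric within tolerance", "not_ultrametric")
  invisible(tree)
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted: the mean of all off-diagonal patristic distances among the
#' community's species.  Abundance-weighted: `sum_{i!=j} a_i a_j d_ij /
#' sum_{i!=j} a_i a_j` — self pairs are excluded and the weights
#' renormalised over the included pairs.
#'
#' @param community a `community` object or named abundance vector.
#' @param tree an [ape::phylo] tree, or a precomputed patristic matrix
#'   covering the community's species.
#' @param abundance_weighted weight pairs by relative basal area?
#' @return MPD in branch-length units, or `NA` (with a warning) for
#'   communities of fewer than 2 species.
#' @export
mpd <- function(community, tree, abundance_weighted = TRUE) {
  w <- community_weights(community)
  if (length(w) < 2L) {
    warn_facetdiv("MPD undefined for < 2 species; returning NA",
                  "undefined_metric")
    return(NA_real_)
  }
  d <- as_patristic(tree, names(w))
  if (abundance_weighted) {
    a <- w / sum(w)
    num <- drop(a %*% d %*% a)        # diag(d) = 0, so self pairs drop out
    den <- 1 - sum(a^2)
    num / den
  } else {
    mean(d[upper.tri(d)])
  }
}

#' Mean nearest taxon distance (MNTD)
#'
#' For each community species, the patristic distance to its closest other
#' community member, averaged (optionally abundance-weighted) over species.
#'
#' @inheritParams mpd
#' @return MNTD in branch-length units, or `NA` for < 2 species.
#' @export
mntd <- function(community, tree, abundance_weighted = TRUE) {
  w <- community_weights(community)
  if (length(w) < 2L) {
    warn_facetdiv("MNTD undefined for < 2 species; returning NA",
                  "undefined_metric")
    return(NA_real_)
  }
  d <- as_patristic(tree, names(w))
  diag(d) <- Inf
  nearest <- apply(d, 1L, min)
  if (abundance_weighted) sum(w / sum(w) * nearest) else mean(nearest)
}

#' Faith's phylogenetic diversity (PD), root-inclusive
#'
#' Total branch length of the minimal subtree connecting the community's
#' tips to the root.  The root-inclusive convention makes PD well defined
#' (the root-to-tip path length) for single-species communities.
#'
#' @inheritParams mpd
#' @param tree an [ape::phylo] tree (a distance matrix is not sufficient).
#' @return summed branch length `>= 0`.
#' @export
faith_pd <- function(community, tree) {
  w <- community_weights(community)
  if (length(w) == 0L)
    stop_facetdiv("empty community", "empty_community")
  bad <- setdiff(names(w), tree$tip.label)
  if (length(bad))
    stop_facetdiv(paste0("species not in tree: ", paste(bad, collapse = ", ")),
                  "missing_tip")
  ntip <- length(tree$tip.label)
  marked <- logical(ntip + tree$Nnode)
  marked[match(names(w), tree$tip.label)] <- TRUE
  # postorder sweep: an edge is in the spanning subtree iff any marked tip
  # lies below it
  post <- ape::reorder.phylo(tree, "postorder")
  keep <- logical(nrow(post$edge))
  for (i in seq_len(nrow(post$edge))) {
    child <- post$edge[i, 2L]
    if (marked[child]) {
      keep[i] <- TRUE
      marked[post$edge[i, 1L]] <- TRUE
    }
  }
  sum(post$edge.length[keep])
}

as_patristic <- function(tree, species) {
  if (is.matrix(tree)) {
    bad <- setdiff(species, rownames(tree))
    if (length(bad))
      stop_facetdiv(paste0("species not in distance matrix: ",
                           paste(bad, collapse = ", ")), "missing_tip")
    tree[species, species, drop = FALSE]
  } else {
    patristic_matrix(tree, species)
  }
}

#' Frequency null model and standardized effect size of MPD
#'
#' Randomises each species' abundances among the plots where it occurs,
#' keeping its occurrence pattern (which plots it is present in) fixed, and
#' recomputes the abundance-weighted MPD of every plot at each iteration.
#' The standardized effect size is `(observed - null mean) / null sd`.
#'
#' @param comm plots-by-species abundance matrix (rownames = plot ids,
#'   colnames = species).
#' @param tree an [ape::phylo] tree or patristic matrix covering the
#'   species.
#' @param n_iter number of randomisations (>= 99; default 999).
#' @param seed integer seed for the randomisation stream.
#' @return data.frame with one row per plot: `mpd_obs`, `null_mean`,
#'   `null_sd`, `ses_mpd`.  Plots whose null distribution is degenerate
#'   (`null_sd == 0`) get `NA` with a warning.
#' @export
frequency_null <- function(comm, tree, n_iter = 999L, seed = 1L) {
  if (!is.matrix(comm) || nrow(comm) < 2L)
    stop_facetdiv("frequency_null() needs a matrix with >= 2 plots",
                  "invalid_argument")
  if (n_iter < 99L)
    stop_facetdiv("n_iter must be >= 99", "invalid_argument")
  d <- as_patristic(tree, colnames(comm))
  obs <- weighted_mpd_rows(comm, d)
  occ <- lapply(seq_len(ncol(comm)), function(j) which(comm[, j] > 0))
  null <- matrix(NA_real_, n_iter, nrow(comm))
  set.seed(as.integer(seed %% 2147483647))
  work <- comm
  for (it in seq_len(n_iter)) {
    for (j in seq_len(ncol(comm))) {
      idx <- occ[[j]]
      if (length(idx) > 1L)
        work[idx, j] <- comm[sample(idx), j]
    }
    null[it, ] <- weighted_mpd_rows(work, d)
  }
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2L, stats::sd)
  ses <- (obs - null_mean) / null_sd
  degenerate <- !is.na(null_sd) & null_sd == 0
  if (any(degenerate)) {
    warn_facetdiv("null sd is zero for some plots; their ses_mpd is NA",
                  "degenerate_null")
    ses[degenerate] <- NA_real_
  }
  data.frame(plot_id = rownames(comm), mpd_obs = obs, null_mean = null_mean,
             null_sd = null_sd, ses_mpd = ses, row.names = NULL)
}

weighted_mpd_row <- function(x, d) {
  sp <- which(x > 0)
  if (length(sp) < 2L) return(NA_real_)
  a <- x[sp] / sum(x[sp])
  drop(a %*% d[sp, sp] %*% a) / (1 - sum(a^2))
}

# Weighted MPD for every row of a plots x species abundance matrix at once.
# Zero abundances contribute nothing to the quadratic form, so the full
# matrix product is equivalent to per-plot subsetting.
weighted_mpd_rows <- function(comm, d) {
  a <- comm / rowSums(comm)
  num <- rowSums((a %*% d) * a)
  den <- 1 - rowSums(a^2)
  out <- num / den
  out[rowSums(comm > 0) < 2L] <- NA_real_
  out
}
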