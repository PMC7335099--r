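#' Relative basal-area abundances for one plot census
#'
#' Converts stem records (DBH in cm) into per-species relative abundances in
#' terms of basal area, the abundance currency used throughout the package.
#' Per-stem basal area is `pi * (dbh / 200)^2` square metres.
#'
#' @param census data.frame of stem records for a single plot and census
#'   date, with columns `species` and `dbh_cm` (and optionally `plot_id`,
#'   `census_date`, which are carried through).
#' @return an object of class `community`: a list with `plot_id`,
#'   `census_date`, `weights` (named numeric vector summing to 1) and
#'   `total_ba` (m^2).
#' @export
basal_area_weights <- function(census) {
  if (is.null(census) || nrow(census) == 0L)
    stop_facetdiv("empty census: no stems to weight", "empty_community")
  if (any(!is.finite(census$dbh_cm)) || any(census$dbh_cm < 10))
    stop_facetdiv("all stems must have finite DBH >= 10 cm", "invalid_argument")
  ba <- pi * (census$dbh_cm / 200)^2
  by_sp <- tapply(ba, as.character(census$species), sum)
  total <- sum(by_sp)
  structure(list(
    plot_id = as.character(census$plot_id[1L] %||% NA_character_),
    census_date = as.numeric(census$census_date[1L] %||% NA_real_),
    weights = stats::setNames(as.numeric(by_sp) / total, names(by_sp)),
    total_ba = total
  ), class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> plot %s @ %.2f: %d species, %.3f m2 basal area\n",
              x$plot_id, x$census_date, length(x$weights), x$total_ba))
  invisible(x)
}

check_proportions <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stop_facetdiv("proportions must be finite and non-negative",
                  "invalid_argument")
  s <- sum(p)
  if (s <= 0)
    stop_facetdiv("proportions must have a positive sum", "invalid_argument")
  p / s
}

#' Simpson diversity index
#'
#' `1 - sum(p_i^2)`: the probability that two individuals drawn at random
#' belong to different species.  Accepts proportions or raw counts
#' (internally normalised).
#'
#' @param p numeric vector of proportions or counts.
#' @return value in `[0, 1 - 1/S]`.
#' @export
simpson_index <- function(p) {
  p <- check_proportions(p)
  1 - sum(p^2)
}

#' Hill number of order 2 (inverse Simpson concentration)
#'
#' `1 / sum(p_i^2)`: the effective number of equally-abundant species.
#' Related to [simpson_index()] by `simpson = 1 - 1/hill_q2`.
#'
#' @inheritParams simpson_index
#' @return effective species count `>= 1`.
#' @export
hill_simpson <- function(p) {
  p <- check_proportions(p)
  1 / sum(p^2)
}

#' Gower dissimilarity over a mixed trait table
#'
#' Numeric traits contribute `|x_i - x_j| / range` (range taken over the
#' species subset scored); categorical traits contribute a 0/1 mismatch.
#' Per-pair missing values are excluded with renormalisation over the traits
#' actually compared.  Traits with zero range in the subset are skipped with
#' a warning rather than an error.
#'
#' @param traits data.frame of traits, rownames = species; numeric columns
#'   are treated as quantitative, factor/character columns as categorical.
#' @param species optional character vector restricting (and ordering) the
#'   species scored; defaults to all rows.
#' @return symmetric species-by-species matrix with zero diagonal, entries
#'   in `[0, 1]`.
#' @export
gower_distance <- function(traits, species = rownames(traits)) {
  species <- as.character(species)
  missing <- setdiff(species, rownames(traits))
  if (length(missing))
    stop_facetdiv(paste0("species without trait rows: ",
                         paste(missing, collapse = ", ")), "missing_traits")
  if (length(species) < 2L)
    stop_facetdiv("gower_distance() needs at least 2 species",
                  "invalid_argument")
  tr <- traits[species, , drop = FALSE]
  n <- length(species)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_along(tr)) {
    v <- tr[[j]]
    if (is.numeric(v)) {
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warn_facetdiv(sprintf("trait '%s' has zero range in this community; skipped",
                              names(tr)[j]), "zero_range_trait")
        next
      }
      d <- abs(outer(v, v, "-")) / rng
    } else {
      v <- as.character(v)
      d <- 1 - outer(v, v, "==")
      mode(d) <- "numeric"
      d[is.na(v), ] <- NA
      d[, is.na(v)] <- NA
    }
    ok <- !is.na(d)
    d[!ok] <- 0
    num <- num + d
    den <- den + ok
  }
  if (all(den == 0))
    stop_facetdiv("no usable traits for Gower distance", "invalid_argument")
  out <- ifelse(den > 0, num / den, NA_real_)
  diag(out) <- 0
  dimnames(out) <- list(species, species)
  out
}

# Principal-coordinates embedding of a dissimilarity matrix.  Negative
# eigenvalues (non-Euclidean input) are handled by re-embedding sqrt(d),
# which is Euclidean for Gower dissimilarities.  Returns a species x axis
# coordinate matrix reproducing the (possibly corrected) distances.
pcoa_embed <- function(d, tol = 1e-9) {
  embed_once <- function(d) {
    n <- nrow(d)
    a <- -0.5 * d^2
    g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
    e <- eigen((g + t(g)) / 2, symmetric = TRUE)
    e
  }
  e <- embed_once(d)
  scale0 <- max(abs(e$values), tol)
  if (min(e$values) < -tol * scale0) {
    d <- sqrt(d)
    e <- embed_once(d)
  }
  keep <- e$values > tol * max(e$values, tol)
  if (!any(keep)) return(matrix(0, nrow(d), 1L, dimnames = list(rownames(d), NULL)))
  x <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
  rownames(x) <- rownames(d)
  x
}

# Standardized (z-score, n-1 denominator) numeric trait space.
standardize_traits <- function(traits, species) {
  tr <- traits[species, , drop = FALSE]
  num <- vapply(tr, is.numeric, logical(1L))
  x <- as.matrix(tr[, num, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep))
    warn_facetdiv("dropping zero-variance numeric trait(s) before standardization",
                  "zero_range_trait")
  x <- x[, keep, drop = FALSE]
  scale(x)
}

#' Functional dispersion (FDis) of a community
#'
#' Abundance-weighted mean distance of species to the community's weighted
#' centroid in trait space: `FDis = sum(a_j z_j) / sum(a_j)` with
#' `z_j = ||x_j - c||` and `c = sum(a_j x_j)`.  With purely numeric traits
#' the space is the z-score standardized (n-1 denominator) Euclidean trait
#' space; with mixed traits it is a principal-coordinates embedding of the
#' Gower dissimilarities (square-root correction when the input is not
#' Euclidean-embeddable).
#'
#' @param traits trait data.frame (rownames = species).
#' @param community a `community` object from [basal_area_weights()], or a
#'   named numeric vector of abundances.
#' @return non-negative scalar; 0 for a single-species community.
#' @export
fdis <- function(traits, community) {
  w <- community_weights(community)
  if (length(w) == 0L)
    stop_facetdiv("empty community", "empty_community")
  if (length(w) == 1L) return(0)
  sp <- names(w)
  missing <- setdiff(sp, rownames(traits))
  if (length(missing))
    stop_facetdiv(paste0("species without trait rows: ",
                         paste(missing, collapse = ", ")), "missing_traits")
  numeric_only <- all(vapply(traits, is.numeric, logical(1L))) &&
    !anyNA(traits[sp, , drop = FALSE])
  x <- if (numeric_only) standardize_traits(traits, sp)
       else pcoa_embed(gower_distance(traits, sp))
  a <- w / sum(w)
  centroid <- drop(a %*% x)
  z <- sqrt(rowSums(sweep(x, 2L, centroid)^2))
  sum(a * z)
}

#' Rao's quadratic entropy
#'
#' `sum_i sum_j a_i a_j d_ij`: the expected trait dissimilarity between two
#' randomly drawn individuals.  Distances are plain (not squared) Gower
#' dissimilarities when computed from a trait table.
#'
#' @param d species-by-species dissimilarity matrix (e.g. from
#'   [gower_distance()]).
#' @param community a `community` object or named abundance vector; names
#'   must index rows of `d`.
#' @return non-negative scalar; 0 for a single-species community.
#' @export
rao_q <- function(d, community) {
  w <- community_weights(community)
  if (length(w) == 0L)
    stop_facetdiv("empty community", "empty_community")
  if (length(w) == 1L) return(0)
  a <- w / sum(w)
  sp <- names(a)
  if (!all(sp %in% rownames(d)))
    stop_facetdiv("distance matrix does not cover all community species",
                  "missing_traits")
  drop(a %*% d[sp, sp] %*% a)
}

#' Basal-area trait coverage per trait
#'
#' Fraction of a community's relative basal area held by species with a
#' non-missing value for each trait.  Emits a warning (but still returns)
#' for traits below `threshold`.
#'
#' @inheritParams fdis
#' @param threshold warn when coverage falls below this fraction
#'   (default 0.9).
#' @return named numeric vector of per-trait coverages in `[0, 1]`.
#' @export
trait_coverage <- function(traits, community, threshold = 0.9) {
  w <- community_weights(community)
  a <- w / sum(w)
  # species entirely absent from the table index as NA rows, i.e. missing
  # for every trait, which is the intended accounting
  cov <- vapply(names(traits), function(tn) {
    v <- traits[names(a), tn]
    sum(a[!is.na(v)])
  }, numeric(1L))
  low <- cov < threshold
  if (any(low))
    warn_facetdiv(sprintf("trait coverage below %.0f%% for: %s", 100 * threshold,
                          paste(names(cov)[low], collapse = ", ")),
                  "low_trait_coverage")
  cov
}

community_weights <- function(community) {
  w <- if (inherits(community, "community")) community$weights else community
  if (is.null(names(w)) && length(w) > 0L)
    stop_facetdiv("abundances must be named by species", "invalid_argument")
  w <- w[w > 0]
  if (length(w) && abs(sum(w) - 1) > 1e-8) w <- w / sum(w)
  w
}
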