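#' Correlation pruning of candidate drivers
#'
#' Iteratively removes one member of every driver pair whose absolute
#' Pearson correlation exceeds the threshold (strictly), keeping the member
#' listed earlier in `priority` (the "more ecologically meaningful" choice,
#' which is a configuration decision, not an algorithmic one).  Constant
#' drivers are dropped with a warning before any correlation is computed.
#'
#' @param drivers data.frame of numeric candidate drivers (rows = plots).
#' @param threshold absolute-correlation cutoff; pairs with `|r| >
#'   threshold` (strict) trigger a drop.  Default 0.7.
#' @param priority character vector ranking driver names from most to least
#'   preferred; defaults to column order.
#' @return list with `retained` (character vector, original order) and
#'   `dropped` (named character vector: dropped name -> reason).
#' @export
prune_correlated <- function(drivers, threshold = 0.7,
                             priority = names(drivers)) {
  if (ncol(drivers) < 2L || nrow(drivers) < 3L)
    stop_facetdiv("need >= 2 drivers and >= 3 plots", "invalid_argument")
  dropped <- character(0)
  constant <- vapply(drivers, function(v) stats::sd(v) == 0, logical(1L))
  if (any(constant)) {
    warn_facetdiv(paste0("dropping constant driver(s): ",
                         paste(names(drivers)[constant], collapse = ", ")),
                  "constant_driver")
    dropped[names(drivers)[constant]] <- "constant"
    drivers <- drivers[, !constant, drop = FALSE]
  }
  rank_of <- function(nm) match(nm, priority, nomatch = length(priority) + 1L)
  repeat {
    if (ncol(drivers) < 2L) break
    cm <- abs(stats::cor(drivers))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- colnames(cm)[worst]
    loser <- pair[which.max(rank_of(pair))]
    dropped[loser] <- sprintf("|r| = %.3f with %s", max(cm),
                              setdiff(pair, loser))
    drivers <- drivers[, colnames(drivers) != loser, drop = FALSE]
  }
  list(retained = names(drivers), dropped = dropped)
}

#' Principal component analysis of plot-level soil variables
#'
#' Centres and scales every soil variable to unit variance, performs a PCA,
#' and selects the axes explaining at least `min_fraction` (default 10%) of
#' the variance.  Each axis is oriented so that its largest-magnitude
#' loading is positive, making loading tables reproducible across
#' platforms.
#'
#' @param soils data.frame with a `plot_id` column and numeric soil
#'   variables (one row per plot).
#' @param min_fraction minimum variance fraction for an axis to be selected.
#' @return object of class `soil_pca`: list with `loadings`, `scores`
#'   (rownames = plot ids), `variance_fraction`, `selected_axes`.
#' @export
soil_pca <- function(soils, min_fraction = 0.10) {
  vars <- soils[, setdiff(names(soils), "plot_id"), drop = FALSE]
  if (nrow(vars) < 4L || ncol(vars) < 3L)
    stop_facetdiv("need >= 4 plots and >= 3 soil variables", "invalid_argument")
  sds <- vapply(vars, stats::sd, numeric(1L))
  if (all(sds == 0))
    stop_facetdiv("all soil variables are constant", "degenerate_input")
  if (any(sds == 0)) {
    warn_facetdiv("dropping constant soil variable(s) before PCA",
                  "constant_driver")
    vars <- vars[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(vars, center = TRUE, scale. = TRUE)
  if (sum(pc$sdev > 1e-12) < 1L)
    stop_facetdiv("soil table is rank deficient", "degenerate_input")
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  rownames(scores) <- as.character(soils$plot_id)
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = frac,
                 selected_axes = which(frac >= min_fraction)),
            class = "soil_pca")
}

#' @export
print.soil_pca <- function(x, ...) {
  cat(sprintf("<soil_pca> %d axes selected (>= 10%% variance): %s\n",
              length(x$selected_axes),
              paste(sprintf("PC%d (%.0f%%)", x$selected_axes,
                            100 * x$variance_fraction[x$selected_axes]),
                    collapse = ", ")))
  invisible(x)
}

#' Enumerate the candidate driver models
#'
#' Builds the deterministic, duplicate-free set of candidate linear model
#' specifications from a grammar over climate drivers and soil PC axes.
#' Every specification includes the plot-area covariate.  The default
#' grammar over three climate drivers and three soil axes yields exactly 35
#' specifications: the covariate-only model; each single driver; climate
#' subsets; soil subsets; each climate driver with all soil axes; the full
#' additive model; and the full model augmented with single PC-by-climate
#' interactions, per-axis interaction blocks, per-driver interaction
#' blocks, and all nine interactions.
#'
#' @param response name of the rate response, e.g. `"d_fdis_r"`.
#' @param climate character vector of climate driver names.
#' @param soil character vector of soil PC axis names.
#' @param covariate always-included covariate (default `"plot_area"`).
#' @return list of `model_spec` objects (`response`, `main`,
#'   `interactions`, `label`).
#' @export
enumerate_models <- function(response,
                             climate = c("d_mcwd_abs", "mcwd_full", "d_vpd_abs"),
                             soil = c("PC1", "PC2", "PC3"),
                             covariate = "plot_area") {
  spec <- function(main, inter = character(0)) {
    main <- unique(c(main, covariate))
    structure(list(response = response, main = main, interactions = inter,
                   label = paste(c(main, inter), collapse = " + ")),
              class = "model_spec")
  }
  subsets <- function(x, sizes) {
    out <- list()
    for (k in sizes[sizes >= 2 & sizes <= length(x)])
      out <- c(out, utils::combn(x, k, simplify = FALSE))
    out
  }
  full <- c(climate, soil)
  all_inter <- as.vector(outer(soil, climate, paste, sep = ":"))
  specs <- c(
    list(spec(character(0))),                                  # covariate only
    lapply(full, spec),                                        # single drivers
    lapply(subsets(climate, seq(2, max(2, length(climate)))), spec),
    lapply(subsets(soil, seq(2, max(2, length(soil)))), spec),
    lapply(climate, function(cl) spec(c(cl, soil))),           # climate + soils
    list(spec(full)),                                          # full additive
    lapply(all_inter, function(i) spec(full, i)),              # + one interaction
    lapply(soil, function(s)                                   # + one axis block
      spec(full, paste(s, climate, sep = ":"))),
    lapply(climate, function(cl)                               # + one driver block
      spec(full, paste(soil, cl, sep = ":"))),
    list(spec(full, all_inter))                                # + all interactions
  )
  labels <- vapply(specs, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    warn_facetdiv("model grammar produced duplicate specifications; de-duplicated",
                  "duplicate_models")
    specs <- specs[!duplicated(labels)]
  }
  specs
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s ~ %s\n", x$response, x$label))
  invisible(x)
}
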