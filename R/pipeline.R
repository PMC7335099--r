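#' Per-plot-census diversity records
#'
#' Computes the functional (FDis, RaoQ), taxonomic (Simpson, Hill q = 2)
#' and phylogenetic (abundance-weighted MPD, MNTD, Faith's PD) diversity of
#' every plot census in a stem table.  All metrics use relative basal area
#' as the abundance currency.
#'
#' @param census stem table (`plot_id`, `census_date`, `species`,
#'   `dbh_cm`).
#' @param traits trait table (rownames = species).
#' @param tree phylogeny covering the census species.
#' @param coverage_threshold trait-coverage warning threshold passed to
#'   [trait_coverage()].
#' @return data.frame with one row per plot census: `plot_id`,
#'   `census_date`, `total_ba`, `richness`, `fdis`, `rao_q`, `simpson`,
#'   `hill_q2`, `mpd`, `mntd`, `pd`.
#' @export
diversity_records <- function(census, traits, tree, coverage_threshold = 0.9) {
  keys <- unique(census[, c("plot_id", "census_date")])
  dmat <- patristic_matrix(tree)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- census$plot_id == keys$plot_id[i] &
      census$census_date == keys$census_date[i]
    comm <- basal_area_weights(census[sel, , drop = FALSE])
    trait_coverage(traits, comm, threshold = coverage_threshold)
    gd <- gower_distance(traits, names(comm$weights))
    data.frame(
      plot_id = comm$plot_id, census_date = comm$census_date,
      total_ba = comm$total_ba, richness = length(comm$weights),
      fdis = fdis(traits, comm),
      rao_q = rao_q(gd, comm),
      simpson = simpson_index(comm$weights),
      hill_q2 = hill_simpson(comm$weights),
      mpd = mpd(comm, dmat),
      mntd = mntd(comm, dmat),
      pd = faith_pd(comm, tree))
  })
  out <- do.call(rbind, rows)
  out[order(out$plot_id, out$census_date), , drop = FALSE]
}

# plots x species basal-area abundance matrix for one census period
community_matrix <- function(census, period = c("first", "last")) {
  period <- match.arg(period)
  plots <- unique(census$plot_id)
  species <- sort(unique(as.character(census$species)))
  m <- matrix(0, length(plots), length(species),
              dimnames = list(plots, species))
  for (p in plots) {
    d <- census[census$plot_id == p, , drop = FALSE]
    dates <- sort(unique(d$census_date))
    date <- if (period == "first") dates[1L] else dates[length(dates)]
    d <- d[d$census_date == date, , drop = FALSE]
    ba <- tapply(pi * (d$dbh_cm / 200)^2, as.character(d$species), sum)
    m[p, names(ba)] <- ba
  }
  m
}

#' Run the full analysis pipeline on a synthetic or supplied world
#'
#' Executes the study stages in dependency order: diversity per plot
#' census; climate climatologies and absolute driver changes; annual rates
#' with the dry/wet split; Bayesian two-group estimation of the dry-wet
#' difference per facet; and driver screening (correlation pruning, soil
#' PCA), model enumeration, fitting and LOO selection for each facet's
#' rate.  A manifest of every effective parameter is attached (and written
#' when `dir` is given).
#'
#' @param world a world from [simulate_study()] (or an equivalently shaped
#'   list of inputs read from disk).
#' @param chains,iter MCMC budget for both the two-group model and the
#'   driver models.
#' @param loo_method `"exact"` (refit per held-out plot; the reference) or
#'   `"tis"` (truncated importance sampling fast path).
#' @param facets rate columns to analyse.
#' @param dry_threshold dry/wet MCWD split in mm.
#' @param seed seed for all inference stages (generation is governed by the
#'   world's own config seed).
#' @param dir optional directory for stage outputs (CSV/JSON).
#' @return list of stage outputs: `diversity`, `climate_summaries`,
#'   `driver_changes`, `soil_pca`, `rates`, `group_comparisons`,
#'   `driver_fits` (per facet: fits, leaderboard, best label), `manifest`.
#' @export
run_pipeline <- function(world, chains = 3L, iter = 2000L,
                         loo_method = c("exact", "tis"),
                         facets = c("d_fdis_r", "d_simpson_r", "d_mpd_r"),
                         dry_threshold = -250, seed = 1L, dir = NULL) {
  loo_method <- match.arg(loo_method)
  div <- diversity_records(world$census, world$traits, world$tree)
  summaries <- climate_summary(world$climate)
  changes <- driver_changes(summaries)
  pca <- soil_pca(world$soils)
  rates <- rate_records(div[, c("plot_id", "census_date", "fdis", "simpson", "mpd")],
                        summaries, threshold = dry_threshold)
  comparisons <- lapply(stats::setNames(facets, facets), function(f)
    compare_groups(rates, f, chains = chains, iter = iter,
                   seed = stage_seed(seed, paste0("best:", f))))
  # driver table: climate changes + selected soil axes + plot area
  drivers <- changes[, c("plot_id", "d_mcwd_abs", "mcwd_full", "d_vpd_abs",
                         "d_spei_abs")]
  sel <- pca$selected_axes
  pcs <- as.data.frame(pca$scores[drivers$plot_id, sel, drop = FALSE])
  names(pcs) <- paste0("PC", sel)
  drivers <- cbind(drivers, pcs)
  drivers$plot_area <- world$plot_info$plot_area[
    match(drivers$plot_id, world$plot_info$plot_id)]
  pruning <- prune_correlated(
    drivers[, setdiff(names(drivers), c("plot_id", "plot_area")), drop = FALSE],
    priority = c("d_mcwd_abs", "mcwd_full", "d_vpd_abs",
                 paste0("PC", sel), "d_spei_abs"))
  model_data <- cbind(drivers, rates[match(drivers$plot_id, rates$plot_id),
                                     facets, drop = FALSE])
  climate_terms <- intersect(c("d_mcwd_abs", "mcwd_full", "d_vpd_abs",
                               "d_spei_abs"), pruning$retained)
  soil_terms <- intersect(paste0("PC", sel), pruning$retained)
  driver_fits <- lapply(stats::setNames(facets, facets), function(f) {
    specs <- enumerate_models(f, climate = climate_terms, soil = soil_terms)
    fits <- lapply(specs, fit_bayes_lm, data = model_data, chains = chains,
                   iter = iter, seed = stage_seed(seed, paste0("lm:", f)))
    board <- loo_compare(fits, model_data, method = loo_method)
    best <- fits[[match(board$label[1L], vapply(fits, function(x) x$spec$label,
                                                character(1L)))]]
    list(fits = fits, leaderboard = board, best = best)
  })
  manifest <- list(
    config = unclass(world$config),
    dry_threshold = dry_threshold, correlation_cutoff = 0.7,
    coverage_threshold = 0.9,
    mcmc = list(chains = chains, iter = iter, seed = seed),
    loo_method = loo_method,
    selected_soil_axes = sel,
    pruned_drivers = as.list(pruning$dropped),
    n_candidate_models = length(driver_fits[[1L]]$fits))
  run <- list(diversity = div, climate_summaries = summaries,
              driver_changes = changes, soil_pca = pca, rates = rates,
              group_comparisons = comparisons, driver_fits = driver_fits,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(div, file.path(dir, "diversity.csv"), row.names = FALSE)
    utils::write.csv(summaries, file.path(dir, "climate_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(changes, file.path(dir, "driver_changes.csv"),
                     row.names = FALSE)
    utils::write.csv(rates, file.path(dir, "rates.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report_run(run), file.path(dir, "report.txt"))
  }
  run
}

#' Human-readable summary of a pipeline run
#'
#' One block per facet for the dry-versus-wet comparison (posterior median
#' difference, HDIs and probability of direction) and one per facet for the
#' selected driver model (coefficient medians, 89% HDIs, ROPE, Rhat),
#' followed by diagnostics (trait coverage and convergence flags are
#' surfaced by the pipeline itself as warnings).
#'
#' @param run output of [run_pipeline()].
#' @return character vector of report lines.
#' @export
report_run <- function(run) {
  lines <- c("== Dry vs wet: annual rates of diversity change ==")
  for (f in names(run$group_comparisons)) {
    cmp <- run$group_comparisons[[f]]
    lines <- c(lines, sprintf(
      "%-12s diff (dry - wet): median %+.3e  50%% HDI [%+.3e, %+.3e]  89%% [%+.3e, %+.3e]  95%% [%+.3e, %+.3e]  Prob %.1f%%%s",
      f, cmp$median_diff, cmp$hdi_50[1L], cmp$hdi_50[2L],
      cmp$hdi_89[1L], cmp$hdi_89[2L], cmp$hdi_95[1L], cmp$hdi_95[2L],
      cmp$prob, if (cmp$converged) "" else "  ** NOT CONVERGED **"))
  }
  lines <- c(lines, "", "== Selected driver models (lowest LOOIC) ==")
  for (f in names(run$driver_fits)) {
    df <- run$driver_fits[[f]]
    lines <- c(lines, sprintf("%s: %s  (LOOIC %.1f, ELPD %.1f, R2_adj %.2f)",
                              f, df$best$spec$label,
                              df$leaderboard$looic[1L],
                              df$leaderboard$elpd[1L], df$best$r2_adj))
    tab <- df$best$coef
    for (j in seq_len(nrow(tab)))
      lines <- c(lines, sprintf(
        "  %-22s median %+.3e  89%% HDI [%+.3e, %+.3e]  ROPE %.2f  Rhat %.2f",
        tab$term[j], tab$median[j], tab$hdi89_l[j], tab$hdi89_h[j],
        tab$rope[j], tab$rhat[j]))
  }
  lines
}
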