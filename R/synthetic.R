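#' Configuration for a synthetic study world
#'
#' Bundles the parameters of the synthetic-data generator, which emulates a
#' network of two-census 1-ha forest plots spanning a wet-dry water-deficit
#' gradient with a multidecadal drying trend.  Defaults describe the study
#' conditions: 21 plots, first census around 1990, second around 2012
#' (interval always >= 10 years), baseline MCWD spanning roughly -300 to
#' -100 mm, and drying-driven declines in diversity that are stronger at
#' the dry end of the gradient.
#'
#' @param n_plots number of plots (>= 2; default 21).
#' @param n_species_pool species-pool size (default 120).
#' @param census_years baseline pair of decimal years `c(t1, t2)`
#'   (default `c(1990, 2012)`; per-plot jitter of +/-2 and +/-1 years is
#'   applied, keeping every interval >= 10).
#' @param mcwd_gradient range `c(dry, wet)` of baseline (noise-free) MCWD
#'   in mm (default `c(-300, -100)`).
#' @param drying_effect named vector of true coupling coefficients linking
#'   a plot's absolute MCWD change (mm) to its true annual rate of change
#'   in each diversity facet (per mm per year; positive couples stronger
#'   drying to faster decline).
#' @param rate_noise_sd named vector of plot-level noise standard
#'   deviations on the true annual rates.
#' @param precip_trend precipitation trend at the wet end of the gradient,
#'   in mm/month per year (negative = drying).
#' @param trend_gradient how much stronger the trend is at the dry end
#'   (multiplier on `precip_trend` reached at the dry extreme).
#' @param climate_noise_sd multiplicative noise sd on monthly
#'   precipitation.
#' @param stems_per_plot approximate stem count per plot census.
#' @param richness approximate species richness per plot.
#' @param trait_bm_sigma2 Brownian-motion rate used for numeric traits.
#' @param seed master integer seed; every generated quantity is
#'   reproducible from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_plots = 21L,
                       n_species_pool = 120L,
                       census_years = c(1990, 2012),
                       mcwd_gradient = c(-300, -100),
                       drying_effect = c(fdis = 1e-4, simpson = 4e-5,
                                         mpd = 2e-4),
                       rate_noise_sd = c(fdis = 2.5e-4, simpson = 1e-4,
                                         mpd = 5e-4),
                       precip_trend = -0.065,
                       trend_gradient = 3.5,
                       climate_noise_sd = 0.08,
                       stems_per_plot = 500L,
                       richness = 80L,
                       trait_bm_sigma2 = 1,
                       seed = 1L) {
  if (n_plots < 2L)
    stop_facetdiv("n_plots must be >= 2", "invalid_argument")
  if (diff(census_years) < 10)
    stop_facetdiv("census interval must be >= 10 years", "invalid_argument")
  if (mcwd_gradient[1L] >= 0)
    stop_facetdiv("mcwd_gradient must include negative (deficit) baselines",
                  "invalid_argument")
  structure(list(
    n_plots = as.integer(n_plots), n_species_pool = as.integer(n_species_pool),
    census_years = census_years, mcwd_gradient = sort(mcwd_gradient),
    drying_effect = drying_effect, rate_noise_sd = rate_noise_sd,
    precip_trend = precip_trend, trend_gradient = trend_gradient,
    climate_noise_sd = climate_noise_sd,
    stems_per_plot = as.integer(stems_per_plot),
    richness = as.integer(richness),
    trait_bm_sigma2 = trait_bm_sigma2, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth, rate 1) tree rescaled to unit height, so patristic
#' distances are on a common relative scale across simulations.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return an ultrametric [ape::phylo] tree with tips `sp001`, `sp002`, ...
#' @export
generate_phylogeny <- function(n_tips, seed = 1L) {
  if (n_tips < 2L)
    stop_facetdiv("n_tips must be >= 2", "invalid_argument")
  set.seed(stage_seed(seed, "phylogeny"))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Simulate traits with controlled phylogenetic signal
#'
#' Numeric traits evolve along the tree under Brownian motion (`"BM"`) or
#' are drawn independently of it (`"white_noise"`); categorical traits
#' (`"categorical:k"`) threshold a latent Brownian trait into `k` classes
#' at equally spaced quantiles, giving them phylogenetic structure too.
#'
#' @param tree an [ape::phylo] tree.
#' @param regime named character vector mapping trait name to one of
#'   `"BM"`, `"white_noise"`, `"categorical:<k>"`.
#' @param seed integer seed.
#' @param bm_sigma2 Brownian-motion rate for numeric and latent traits.
#' @return data.frame of traits, rownames = tip labels; categorical traits
#'   are factors; no missing values.
#' @export
generate_traits <- function(tree,
                            regime = c(wood_density = "BM", sla = "BM",
                                       leaf_n = "BM", height_max = "BM",
                                       deciduous = "categorical:2",
                                       guild = "categorical:3",
                                       n_fixing = "categorical:2"),
                            seed = 1L, bm_sigma2 = 1) {
  ok <- grepl("^(BM|white_noise|categorical:[0-9]+)$", regime)
  if (!all(ok))
    stop_facetdiv(paste0("unknown trait regime: ",
                         paste(regime[!ok], collapse = ", ")),
                  "invalid_argument")
  set.seed(stage_seed(seed, "traits"))
  out <- lapply(names(regime), function(nm) {
    r <- regime[[nm]]
    if (r == "BM") {
      as.numeric(ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_sigma2)))
    } else if (r == "white_noise") {
      stats::rnorm(length(tree$tip.label))
    } else {
      k <- as.integer(sub("categorical:", "", r))
      latent <- as.numeric(ape::rTraitCont(tree, model = "BM",
                                           sigma = sqrt(bm_sigma2)))
      cuts <- stats::quantile(latent, probs = seq(0, 1, length.out = k + 1L))
      cuts[1L] <- -Inf
      cuts[k + 1L] <- Inf
      factor(cut(latent, cuts, labels = paste0(nm, "_", seq_len(k))))
    }
  })
  names(out) <- names(regime)
  df <- as.data.frame(out)
  rownames(df) <- tree$tip.label
  df
}

#' Simulate monthly climate series along the water-deficit gradient
#'
#' Monthly precipitation, PET and VPD for every plot over 1964-2013:
#' a seasonal sinusoid whose mean is calibrated (per plot) so the
#' noise-free baseline MCWD matches the plot's position on the
#' `mcwd_gradient`, a linear drying trend that is stronger at the dry end
#' of the gradient, and multiplicative noise.  PET is a fixed seasonal
#' cycle around 100 mm/month; VPD increases with site dryness and with the
#' drying trend.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `plot_id`, `year`, `month`, `precip_mm`,
#'   `pet_mm`, `vpd_kpa`.
#' @export
generate_climate <- function(config) {
  set.seed(stage_seed(config$seed, "climate"))
  years <- 1964:2013
  months <- 1:12
  nm <- length(years) * 12L
  # dryness in [0, 1]: 1 at the dry end of the gradient
  dryness <- if (config$n_plots == 1L) 0.5 else
    rev(seq(0, 1, length.out = config$n_plots))
  # plot-level noise on the baseline keeps the site's long-term water
  # deficit from being a deterministic function of its drying trend
  baseline_mcwd <- config$mcwd_gradient[2L] +
    dryness * (config$mcwd_gradient[1L] - config$mcwd_gradient[2L]) +
    stats::rnorm(config$n_plots, 0, 25)
  baseline_mcwd <- pmin(baseline_mcwd, -20)
  pet <- 100 + 10 * cos(2 * pi * (months - 2) / 12)
  season <- cos(2 * pi * (months - 9) / 12)   # wet peak in September
  amp <- 90
  # plot-level idiosyncrasy in trend strength and atmospheric drying, so
  # baseline dryness, precipitation trend and VPD trend are related but not
  # collinear across plots (as in real driver sets that survive
  # correlation screening)
  trend_jitter <- pmin(pmax(exp(stats::rnorm(config$n_plots, 0, 0.5)),
                            0.55), 1.5)
  vpd_trend <- 0.0015 * stats::runif(config$n_plots, 0.4, 1.6) +
    0.001 * dryness
  rows <- vector("list", config$n_plots)
  for (i in seq_len(config$n_plots)) {
    # calibrate the mean precipitation so the stationary MCWD equals the
    # plot's baseline (closed under the cumulative-deficit recursion,
    # because the deficit season is contiguous for a sinusoid)
    target <- baseline_mcwd[i]
    f <- function(pbar) sum(pmin(0, pbar + amp * season - pet)) - target
    pbar <- stats::uniroot(f, c(1, 500))$root
    trend <- config$precip_trend * trend_jitter[i] *
      (1 + (config$trend_gradient - 1) * dryness[i])     # mm/month per yr
    tgrid <- rep(years - 1964, each = 12L)
    p <- pbar + rep(amp * season, length(years)) + trend * tgrid
    p <- p * exp(stats::rnorm(nm, 0, config$climate_noise_sd))
    p <- pmax(p, 0)
    vpd <- 0.7 + 0.6 * dryness[i] - rep(0.25 * season, length(years)) +
      vpd_trend[i] * tgrid + stats::rnorm(nm, 0, 0.02)
    rows[[i]] <- data.frame(
      plot_id = sprintf("P%02d", i),
      year = rep(years, each = 12L), month = rep(months, length(years)),
      precip_mm = p, pet_mm = rep(pet, length(years)),
      vpd_kpa = pmax(vpd, 0.05))
  }
  do.call(rbind, rows)
}

#' Simulate a plot-level soil table with a three-axis latent structure
#'
#' Nine soil variables (eCEC, Mg, N, pH, Fe, Ca, P, %Clay, %Sand) generated
#' from three latent factors — a cations-nutrients factor, an
#' acidity-calcium factor and a texture factor — plus independent noise.
#' %Clay and %Sand stay in `[0, 100]` and sum to at most 100.
#'
#' @param n_plots number of plots (>= 4).
#' @param seed integer seed.
#' @param noise_sd sd of the independent noise added to each variable (on
#'   the latent scale; 0 gives an exactly rank-3 table).
#' @return data.frame with `plot_id` and the nine soil variables.
#' @export
generate_soils <- function(n_plots, seed = 1L, noise_sd = 0.3) {
  if (n_plots < 4L)
    stop_facetdiv("n_plots must be >= 4", "invalid_argument")
  set.seed(stage_seed(seed, "soils"))
  f <- matrix(stats::rnorm(n_plots * 3L), n_plots, 3L)
  eps <- function() stats::rnorm(n_plots, 0, noise_sd)
  ecec <- 20 + 4 * f[, 1L] + eps()
  mg <- 5 + 1.5 * f[, 1L] + eps()
  n_tot <- 0.2 + 0.05 * f[, 1L] + 0.01 * eps()
  ph <- 5.5 - 0.6 * f[, 2L] + 0.2 * eps()
  fe <- 40 + 8 * f[, 2L] + 2 * eps()
  ca <- 8 - 2 * f[, 2L] + eps()
  p_soil <- 80 + 25 * f[, 1L] + 5 * eps()
  sand <- 50 + 12 * f[, 3L] + 2 * eps()
  clay <- 30 - 10 * f[, 3L] + 2 * eps()
  sand <- pmin(pmax(sand, 0), 100)
  clay <- pmin(pmax(clay, 0), 100)
  over <- sand + clay > 100
  if (any(over)) {
    shrink <- 100 / (sand[over] + clay[over])
    sand[over] <- sand[over] * shrink
    clay[over] <- clay[over] * shrink
  }
  data.frame(plot_id = sprintf("P%02d", seq_len(n_plots)),
             ecec_mmol_kg = ecec, mg_mmol_kg = mg, n_total_pct = n_tot,
             ph = ph, fe_mmol_kg = fe, ca_mmol_kg = ca, p_mg_kg = p_soil,
             clay_pct = clay, sand_pct = sand)
}

# --- community construction -------------------------------------------------

# Turn target species weights into a stem table whose realized basal-area
# weights equal the targets exactly: each species gets a stem count
# proportional to its weight and a uniform DBH solving its basal-area share.
weights_to_stems <- function(weights, plot_id, census_date,
                             total_ba = 30, n_stems = 500L) {
  w <- weights / sum(weights)
  n_j <- pmax(1L, round(w * n_stems))
  ba_j <- w * total_ba
  dbh_j <- 200 * sqrt(ba_j / (n_j * pi))
  if (any(dbh_j < 10)) {
    # species whose share implies a sub-minimum stem get one 10 cm stem;
    # the weight distortion is < 0.1% of basal area
    small <- dbh_j < 10
    n_j[small] <- 1L
    dbh_j[small] <- 10
  }
  data.frame(
    plot_id = plot_id,
    census_date = census_date,
    stem_id = sprintf("%s_%s_%d", plot_id, format(census_date), sequence(n_j)),
    species = rep(names(w), n_j),
    dbh_cm = rep(dbh_j, n_j))
}

# Metric evaluations on a weight vector over a fixed community support:
# embedding (trait space) and patristic matrix are computed once from the
# species set, so the solver and the analysis functions agree exactly.
facet_values <- function(w, embed, dmat) {
  a <- w / sum(w)
  centroid <- drop(a %*% embed)
  z <- sqrt(rowSums(sweep(embed, 2L, centroid)^2))
  c(simpson = 1 - sum(a^2),
    fdis = sum(a * z),
    mpd = drop(a %*% dmat %*% a) / (1 - sum(a^2)))
}

# Reallocated weights: rank-preserving concentration (power theta) plus
# exponential tilts along the trait-distance (eta, eta2) and
# mean-phylo-distance (zeta, zeta2) axes; the quadratic terms give the
# solver enough freedom to steer the three facets independently.
realloc_weights <- function(w0, theta, eta, zeta, zscore, mscore,
                            eta2 = 0, zeta2 = 0) {
  lw <- theta * log(w0) + eta * zscore + zeta * mscore +
    eta2 * zscore^2 + zeta2 * mscore^2
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

# Solve (log theta, eta, zeta, eta2, zeta2) jointly so the reallocated
# community hits the target facet values, by Nelder-Mead on the squared
# relative gaps with restarts.  With strict = TRUE, a residual beyond tol
# (fraction of the start-to-target span, default the generator's 10%
# accuracy contract) raises an infeasible-target error; otherwise the
# nearest achievable combination is returned (the caller records realized
# rates as ground truth).
solve_reallocation <- function(w0, embed, dmat, targets, tol = 0.1,
                               strict = TRUE) {
  start <- facet_values(w0, embed, dmat)
  span <- pmax(abs(targets - start), 1e-4)
  if (all(abs(targets - start) < 1e-14)) return(w0)
  zscore <- {
    a <- w0 / sum(w0)
    centroid <- drop(a %*% embed)
    z <- sqrt(rowSums(sweep(embed, 2L, centroid)^2))
    as.numeric(scale(z))
  }
  mscore <- as.numeric(scale(drop(dmat %*% (w0 / sum(w0)))))
  weights_at <- function(par)
    realloc_weights(w0, exp(par[1L]), par[2L], par[3L], zscore, mscore,
                    par[4L], par[5L])
  obj <- function(par) {
    v <- facet_values(weights_at(par), embed, dmat)
    sum(((v - targets) / span)^2)
  }
  inits <- list(c(0, 0, 0, 0, 0), c(0.2, -0.5, -0.5, 0, 0),
                c(-0.2, 0.5, 0.5, 0, 0), c(0.4, -1, -1, 0.2, 0.2),
                c(0.5, 1, -1, 0.5, -0.5), c(-0.5, -1, 1, -0.5, 0.5),
                c(0.3, -1.5, 0.5, 1, 0), c(0, 1.5, -0.5, -1, 0.3),
                c(0.6, -0.8, -1.2, 0.4, 0.6), c(-0.4, 0.8, 1.2, -0.4, -0.6))
  best <- NULL
  for (init in inits) {
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < (tol / 10)^2) break
  }
  w <- weights_at(best$par)
  got <- facet_values(w, embed, dmat)
  if (strict && any(abs(got - targets) > tol * span))
    stop_facetdiv("target rates are infeasible for this community",
                  "infeasible_target")
  w
}

#' Simulate paired-census communities with known true rates of change
#'
#' Builds a first-census community per plot (log-normal basal-area
#' abundances over a random species subset), derives each plot's true
#' annual rates of change of Simpson, FDis and MPD from its absolute MCWD
#' change (`rate = drying_effect * dMCWD_Abs + noise`; with a positive
#' coupling, a more negative MCWD change means a faster decline) plus
#' plot-level noise, and engineers the second-census community by abundance
#' reallocation (power concentration plus trait- and phylogeny-aligned
#' tilts) so the realized rates match the true rates, typically to well
#' within 10%.  Drawn rates that exceed what reallocation can achieve for a
#' community are brought to the nearest achievable combination; the
#' realized rates recorded in the ground truth are always exact.  Mathematically
#' impossible targets (Simpson outside `(0, 1 - 1/S)`) raise an
#' infeasible-target error.  Species sets are identical between censuses;
#' stem tables reproduce the intended weights exactly.
#'
#' @param tree phylogeny covering the species pool.
#' @param traits trait table covering the species pool.
#' @param climate output of [generate_climate()] for the same config.
#' @param config a [sim_config()].
#' @return list with `census` (stem table for both censuses, columns
#'   `plot_id`, `census_date`, `stem_id`, `species`, `dbh_cm`),
#'   `plot_info` (`plot_id`, `plot_area`, `t1`, `t2`) and `ground_truth`
#'   (per-plot true and realized rates, the coupling coefficients and the
#'   per-plot `d_mcwd_abs` used; never needed by any analysis stage).
#' @export
generate_community_pair <- function(tree, traits, climate, config) {
  pool <- tree$tip.label
  if (!all(pool %in% rownames(traits)))
    stop_facetdiv("species pool must be covered by the trait table",
                  "invalid_argument")
  set.seed(stage_seed(config$seed, "community"))
  plots <- unique(climate$plot_id)
  dmat_pool <- patristic_matrix(tree)
  # per-plot absolute MCWD change between the two 30-yr climatologies
  d_mcwd <- vapply(plots, function(p) {
    ser <- climate[climate$plot_id == p, , drop = FALSE]
    mcwd(ser, c(1984, 2013)) - mcwd(ser, c(1964, 1993))
  }, numeric(1L))
  census <- list()
  info <- list()
  gt <- list()
  for (i in seq_along(plots)) {
    p <- plots[i]
    t1 <- config$census_years[1L] + stats::runif(1, -2, 2)
    t2 <- config$census_years[2L] + stats::runif(1, -1, 1)
    if (t2 - t1 < 10) t2 <- t1 + 10
    s_i <- min(config$richness, config$n_species_pool)
    sp <- sort(sample(pool, s_i))
    w1 <- stats::rlnorm(s_i, 0, 1.2)
    w1 <- stats::setNames(w1 / sum(w1), sp)
    embed <- pcoa_embed(gower_distance(traits, sp))
    dmat <- dmat_pool[sp, sp]
    v1 <- facet_values(w1, embed, dmat)
    dmc <- d_mcwd[[i]]
    true_rate <- c(
      simpson = config$drying_effect[["simpson"]] * dmc +
        stats::rnorm(1, 0, config$rate_noise_sd[["simpson"]]),
      fdis = config$drying_effect[["fdis"]] * dmc +
        stats::rnorm(1, 0, config$rate_noise_sd[["fdis"]]),
      mpd = config$drying_effect[["mpd"]] * dmc +
        stats::rnorm(1, 0, config$rate_noise_sd[["mpd"]]))
    targets <- v1 + true_rate[c("simpson", "fdis", "mpd")] * (t2 - t1)
    if (targets["simpson"] >= 1 - 1 / s_i || targets["simpson"] <= 0)
      stop_facetdiv("target Simpson rate is infeasible (outside [0, 1 - 1/S])",
                    "infeasible_target")
    w2 <- solve_reallocation(w1, embed, dmat, targets, strict = FALSE)
    v2 <- facet_values(w2, embed, dmat)
    census[[length(census) + 1L]] <-
      weights_to_stems(w1, p, t1, n_stems = config$stems_per_plot)
    census[[length(census) + 1L]] <-
      weights_to_stems(w2, p, t2, n_stems = config$stems_per_plot)
    info[[i]] <- data.frame(plot_id = p,
                            plot_area = round(stats::runif(1, 0.6, 1), 2),
                            t1 = t1, t2 = t2)
    gt[[i]] <- data.frame(plot_id = p, d_mcwd_abs = d_mcwd[i],
                          interval = t2 - t1,
                          true_rate_simpson = true_rate[["simpson"]],
                          true_rate_fdis = true_rate[["fdis"]],
                          true_rate_mpd = true_rate[["mpd"]],
                          realized_rate_simpson = (v2[["simpson"]] - v1[["simpson"]]) / (t2 - t1),
                          realized_rate_fdis = (v2[["fdis"]] - v1[["fdis"]]) / (t2 - t1),
                          realized_rate_mpd = (v2[["mpd"]] - v1[["mpd"]]) / (t2 - t1))
  }
  list(census = do.call(rbind, census),
       plot_info = do.call(rbind, info),
       ground_truth = list(
         plots = do.call(rbind, gt),
         drying_effect = config$drying_effect,
         rate_noise_sd = config$rate_noise_sd))
}

#' Simulate a complete synthetic study and optionally write it to disk
#'
#' Generates the phylogeny, traits, climate, soils and paired-census
#' communities of one synthetic world.  With `dir` set, writes census,
#' traits, climate, soils and plot-info CSVs, the Newick tree and the
#' ground-truth JSON; identical configs produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return list with `tree`, `traits`, `climate`, `soils`, `census`,
#'   `plot_info`, `ground_truth`, `config`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  tree <- generate_phylogeny(config$n_species_pool, seed = config$seed)
  traits <- generate_traits(tree, seed = config$seed,
                            bm_sigma2 = config$trait_bm_sigma2)
  climate <- generate_climate(config)
  soils <- generate_soils(config$n_plots, seed = config$seed)
  comm <- generate_community_pair(tree, traits, climate, config)
  world <- c(list(tree = tree, traits = traits, climate = climate,
                  soils = soils), comm, list(config = config))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name)
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    wcsv(world$census, "census.csv")
    tr <- cbind(species = rownames(traits), traits)
    wcsv(tr, "traits.csv")
    wcsv(climate, "climate.csv")
    wcsv(soils, "soils.csv")
    wcsv(world$plot_info, "plot_info.csv")
    ape::write.tree(tree, file.path(dir, "phylogeny.nwk"))
    jsonlite::write_json(world$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         dataframe = "columns", digits = NA)
  }
  world
}
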