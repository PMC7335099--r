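test_that("pure-birth phylogenies are ultrametric, unit-height and reproducible", {
  two <- generate_phylogeny(2, seed = 1)
  expect_equal(two$Nnode, 1L)
  depths <- ape::node.depth.edgelength(two)[1:2]
  expect_equal(depths[1], depths[2], tolerance = 1e-12)

  t1 <- generate_phylogeny(50, seed = 2)
  t2 <- generate_phylogeny(50, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  d <- ape::node.depth.edgelength(t1)[1:50]
  expect_lt(max(d) - min(d), 1e-9)
  expect_equal(max(d), 1, tolerance = 1e-9)   # rescaled to unit height
  expect_true(all(t1$edge.length > 0))

  # ultrametry survives a Newick round trip
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(t1, tmp)
  rt <- ape::read.tree(tmp)
  dr <- ape::node.depth.edgelength(rt)[seq_along(rt$tip.label)]
  expect_lt(max(dr) - min(dr), 1e-9)

  expect_error(generate_phylogeny(1), class = "invalid_argument")
})

test_that("trait regimes are honoured and categorical traits partition the tips", {
  tree <- generate_phylogeny(40, seed = 3)
  tr <- generate_traits(tree, seed = 4)
  expect_equal(rownames(tr), tree$tip.label)
  expect_false(anyNA(tr))
  expect_s3_class(tr$guild, "factor")
  expect_equal(nlevels(tr$guild), 3L)
  expect_equal(nlevels(tr$deciduous), 2L)
  expect_true(all(table(tr$deciduous) > 0))

  expect_error(generate_traits(tree, regime = c(a = "volcanic")),
               class = "invalid_argument")

  expect_identical(generate_traits(tree, seed = 4),
                   generate_traits(tree, seed = 4))
})

test_that("climate series are stationary without trend and drier with one", {
  quiet <- sim_config(n_plots = 3, precip_trend = 0, climate_noise_sd = 0,
                      seed = 5)
  clim <- generate_climate(quiet)
  for (p in unique(clim$plot_id)) {
    ser <- clim[clim$plot_id == p, ]
    expect_equal(mcwd(ser, c(1964, 1993)), mcwd(ser, c(1984, 2013)),
                 tolerance = 1e-9)
  }
  # noise-free baselines span the configured gradient
  base <- vapply(unique(clim$plot_id), function(p)
    mcwd(clim[clim$plot_id == p, ], c(1964, 2013)), numeric(1))
  expect_equal(unname(base[1]), quiet$mcwd_gradient[1], tolerance = 1)
  expect_equal(unname(base[3]), quiet$mcwd_gradient[2], tolerance = 1)

  drying <- sim_config(n_plots = 3, seed = 5)
  clim2 <- generate_climate(drying)
  dc <- driver_changes(climate_summary(clim2))
  expect_true(all(dc$d_mcwd_abs < 0))

  expect_identical(generate_climate(drying), generate_climate(drying))
})

test_that("soil tables have the latent three-axis structure and legal textures", {
  s0 <- generate_soils(25, seed = 6, noise_sd = 0)
  pc <- prcomp(s0[, -1], scale. = TRUE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  expect_true(all(frac[1:3] > 0))
  expect_true(all(frac[4:length(frac)] < 1e-10))

  for (seed in 1:5) {
    s <- generate_soils(21, seed = seed)
    expect_true(all(s$sand_pct >= 0 & s$sand_pct <= 100))
    expect_true(all(s$clay_pct >= 0 & s$clay_pct <= 100))
    expect_true(all(s$sand_pct + s$clay_pct <= 100 + 1e-9))
  }
  expect_identical(generate_soils(21, seed = 2), generate_soils(21, seed = 2))
  expect_error(generate_soils(3), class = "invalid_argument")
})

test_that("zero target rates reproduce the first census diversity exactly", {
  cfg <- sim_config(n_plots = 4, richness = 20, n_species_pool = 40,
                    stems_per_plot = 150,
                    drying_effect = c(fdis = 0, simpson = 0, mpd = 0),
                    rate_noise_sd = c(fdis = 0, simpson = 0, mpd = 0),
                    seed = 7)
  w <- simulate_study(cfg)
  div <- diversity_records(w$census, w$traits, w$tree)
  for (p in unique(div$plot_id)) {
    d <- div[div$plot_id == p, ]
    expect_equal(d$fdis[1], d$fdis[2], tolerance = 1e-12)
    expect_equal(d$simpson[1], d$simpson[2], tolerance = 1e-12)
    expect_equal(d$mpd[1], d$mpd[2], tolerance = 1e-12)
  }
})

test_that("prescribed rates of change are realized by the reallocation solver", {
  cfg <- sim_config(n_plots = 5, richness = 30, n_species_pool = 60,
                    stems_per_plot = 300,
                    rate_noise_sd = c(fdis = 0, simpson = 0, mpd = 0),
                    seed = 8)
  w <- simulate_study(cfg)
  gt <- w$ground_truth$plots
  # recompute the realized rates from the generated stem tables
  div <- diversity_records(w$census, w$traits, w$tree)
  cs <- climate_summary(w$climate)
  rates <- rate_records(div[, c("plot_id", "census_date", "fdis", "simpson",
                                "mpd")], cs)
  m <- match(gt$plot_id, rates$plot_id)
  expect_equal(rates$d_simpson_r[m], gt$true_rate_simpson, tolerance = 0.1)
  expect_equal(rates$d_fdis_r[m], gt$true_rate_fdis, tolerance = 0.1)
  expect_equal(rates$d_mpd_r[m], gt$true_rate_mpd, tolerance = 0.1)
  # every abundance positive, every plot holds basal area
  expect_true(all(w$census$dbh_cm >= 10))
  expect_true(all(tapply(w$census$dbh_cm, w$census$plot_id, length) > 0))
})

test_that("identical configs write byte-identical study files", {
  cfg <- sim_config(n_plots = 4, richness = 25, n_species_pool = 50,
                    stems_per_plot = 100, seed = 9)
  d1 <- file.path(tempdir(), "world_a")
  d2 <- file.path(tempdir(), "world_b")
  simulate_study(cfg, dir = d1)
  simulate_study(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_plots = 1), class = "invalid_argument")
  expect_error(sim_config(census_years = c(2000, 2005)),
               class = "invalid_argument")
  expect_error(sim_config(mcwd_gradient = c(100, 300)),
               class = "invalid_argument")
})
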