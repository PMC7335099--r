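test_that("basal-area weights follow the pi*(dbh/200)^2 formula and add over stems", {
  one <- data.frame(plot_id = "p", census_date = 2000, species = "A",
                    dbh_cm = 10)
  comm <- basal_area_weights(one)
  expect_equal(comm$total_ba, pi * 0.05^2)
  expect_equal(unname(comm$weights), 1)

  two <- data.frame(plot_id = "p", census_date = 2000,
                    species = c("A", "B"), dbh_cm = c(10, 10))
  expect_equal(unname(basal_area_weights(two)$weights), c(0.5, 0.5))

  # two 10 cm stems hold the same basal area as one 10*sqrt(2) cm stem
  add <- data.frame(plot_id = "p", census_date = 2000,
                    species = c("A", "A", "B"),
                    dbh_cm = c(10, 10, 10 * sqrt(2)))
  expect_equal(unname(basal_area_weights(add)$weights), c(0.5, 0.5))

  expect_error(basal_area_weights(one[0, ]), class = "empty_community")
  expect_error(
    basal_area_weights(data.frame(plot_id = "p", census_date = 2000,
                                  species = "A", dbh_cm = 9)),
    class = "invalid_argument")
})

test_that("Simpson and Hill q=2 match closed forms and are exact duals", {
  expect_equal(simpson_index(1), 0)
  expect_equal(simpson_index(rep(1, 4)), 0.75)
  expect_equal(simpson_index(c(2, 1, 1)), 0.625)
  expect_equal(hill_simpson(rep(1, 7)), 7)
  expect_equal(hill_simpson(1), 1)
  expect_equal(hill_simpson(c(2, 1, 1)), 1 / 0.375)
  expect_error(simpson_index(c(0.5, -0.1)), class = "invalid_argument")
  for (s in c(2, 5, 23)) {
    set.seed(s)
    p <- runif(s)
    expect_equal(simpson_index(p), 1 - 1 / hill_simpson(p), tolerance = 1e-12)
  }
})

test_that("Gower distance handles numeric, categorical and degenerate traits", {
  tr <- data.frame(num = c(0, 10, 5), cat = factor(c("x", "x", "y")),
                   row.names = c("A", "B", "C"))
  d <- gower_distance(tr)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d, t(d))
  expect_equal(d["A", "B"], 0.5)            # numeric extremes, same class
  expect_equal(d["A", "C"], 0.75)           # (0.5 numeric + 1 mismatch) / 2

  flat <- data.frame(a = c(1, 1), b = c(0, 4), row.names = c("A", "B"))
  expect_warning(d0 <- gower_distance(flat), class = "zero_range_trait")
  expect_equal(d0["A", "B"], 1)             # distance from the usable trait only
  allflat <- data.frame(a = c(1, 1), b = c(2, 2), row.names = c("A", "B"))
  suppressWarnings(expect_error(gower_distance(allflat),
                                class = "invalid_argument"))

  # missing values are excluded pairwise with renormalisation
  tr$num[3] <- NA
  d2 <- gower_distance(tr)
  expect_equal(d2["A", "C"], 1)             # only the categorical mismatch left
})

test_that("Gower distance agrees with cluster::daisy on mixed data", {
  skip_if_not_installed("cluster")
  set.seed(4)
  tr <- data.frame(x = rnorm(8), y = runif(8),
                   g = factor(sample(c("u", "v"), 8, TRUE)),
                   row.names = paste0("s", 1:8))
  mine <- gower_distance(tr)
  ref <- as.matrix(cluster::daisy(tr, metric = "gower"))
  dimnames(ref) <- dimnames(mine)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("FDis matches hand-derived cases and direct formula evaluation", {
  tr <- data.frame(t1 = c(0, 2), row.names = c("A", "B"))
  expect_equal(fdis(tr, c(A = 0.5, B = 0.5)), 1 / sqrt(2))
  expect_equal(fdis(tr, c(A = 1)), 0)

  # dominance collapse: centroid moves onto the dominant species
  eps_val <- fdis(tr, c(A = 1 - 1e-9, B = 1e-9))
  expect_lt(eps_val, 1e-6)

  set.seed(7)
  tr6 <- data.frame(a = rnorm(6), b = rnorm(6), c = runif(6),
                    row.names = paste0("s", 1:6))
  for (seed in 1:10) {
    n <- sample(2:6, 1)
    sp <- sample(rownames(tr6), n)
    w <- random_community(sp, seed)
    expect_equal(fdis(tr6, w), bf_fdis(tr6[sp, , drop = FALSE], w),
                 tolerance = 1e-10)
  }
})

test_that("FDis is invariant to trait rescaling, species duplication and zero weights", {
  set.seed(8)
  tr <- data.frame(a = rnorm(6), b = runif(6), row.names = paste0("s", 1:6))
  w <- random_community(rownames(tr), 1)
  base <- fdis(tr, w)

  tr2 <- tr
  tr2$a <- tr2$a * 1000 + 77
  expect_equal(fdis(tr2, w), base, tolerance = 1e-10)

  wz <- c(w, s7 = 0)
  tr3 <- rbind(tr, s7 = c(0.1, 0.2))
  expect_equal(fdis(tr3, wz), base, tolerance = 1e-10)

  # splitting one species into two identical halves leaves FDis unchanged
  # (richness insensitivity), checked in the Gower/embedding path
  trc <- data.frame(a = c(tr$a, tr$a[1]), b = c(tr$b, tr$b[1]),
                    g = factor(rep(c("u", "v"), length.out = 7)),
                    row.names = paste0("s", 1:7))
  trc$g[7] <- trc$g[1]
  wsplit <- w
  wsplit[["s1"]] <- w[["s1"]] / 2
  wsplit <- c(wsplit, s7 = w[["s1"]] / 2)
  expect_equal(fdis(trc, wsplit), fdis(trc[1:6, ], w), tolerance = 1e-8)
})

test_that("Rao's Q matches its double sum and tracks FDis over random communities", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(rao_q(d, c(A = 0.5, B = 0.5)), 0.5)
  expect_equal(rao_q(d, c(A = 1)), 0)

  set.seed(9)
  tr <- data.frame(a = rnorm(10), b = runif(10),
                   g = factor(sample(c("u", "v", "w"), 10, TRUE)),
                   row.names = paste0("s", 1:10))
  gd <- gower_distance(tr)
  for (seed in 1:5) {
    sp <- sample(rownames(tr), 5)
    w <- random_community(sp, seed + 100)
    expect_equal(rao_q(gd, w), bf_raoq(w, gd), tolerance = 1e-12)
  }
  # study-like communities: mixed traits with phylogenetic structure,
  # skewed abundances, per-community distances as the pipeline computes them
  tree <- generate_phylogeny(30, seed = 2)
  trs <- generate_traits(tree, seed = 2)
  vals <- t(vapply(1:50, function(s) {
    set.seed(s + 300)
    n <- sample(8:20, 1)
    sp <- sample(rownames(trs), n)
    w <- stats::setNames(rlnorm(n, 0, 1.2), sp)
    w <- w / sum(w)
    c(fdis(trs, w), rao_q(gower_distance(trs, sp), w))
  }, numeric(2)))
  expect_gt(cor(vals[, 1], vals[, 2], method = "spearman"), 0.8)
})

test_that("trait coverage reports basal-area fractions and warns below threshold", {
  tr <- data.frame(a = c(1, 2, NA), b = c(1, 2, 3),
                   row.names = c("A", "B", "C"))
  w <- c(A = 0.4, B = 0.3, C = 0.3)
  expect_warning(cov <- trait_coverage(tr, w), class = "low_trait_coverage")
  expect_equal(unname(cov["a"]), 0.7)
  expect_equal(unname(cov["b"]), 1.0)
  expect_silent(cov2 <- trait_coverage(tr, w, threshold = 0.5))
  expect_equal(unname(cov2["a"]), 0.7)
})

test_that("community metrics are invariant to species ordering", {
  set.seed(10)
  tr <- data.frame(a = rnorm(5), b = runif(5), row.names = paste0("s", 1:5))
  w <- random_community(rownames(tr), 3)
  perm <- sample(names(w))
  expect_equal(fdis(tr, w[perm]), fdis(tr, w), tolerance = 1e-12)
  expect_equal(simpson_index(w[perm]), simpson_index(w))
  gd <- gower_distance(tr)
  expect_equal(rao_q(gd, w[perm]), rao_q(gd, w), tolerance = 1e-12)
})
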