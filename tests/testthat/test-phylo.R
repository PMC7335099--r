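test_that("patristic distances match hand cases and the path-walk oracle", {
  tree <- small_tree()
  d <- patristic_matrix(tree)
  expect_equal(d["A", "B"], 2)              # cherry with pendant lengths 1, 1
  expect_equal(d["A", "C"], 4)              # spans the root of a height-2 tree
  expect_equal(diag(d), setNames(rep(0, 4), tree$tip.label))

  rt <- generate_phylogeny(20, seed = 5)
  expect_equal(patristic_matrix(rt), bf_patristic(rt), tolerance = 1e-12)

  expect_error(patristic_matrix(tree, c("A", "nope")), class = "missing_tip")
})

test_that("MPD and MNTD match closed forms, oracles and conventions", {
  tree <- small_tree()
  w2 <- c(A = 0.3, C = 0.7)
  expect_equal(mpd(w2, tree), 4)            # single pair: their distance
  expect_equal(mntd(w2, tree), 4)

  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  ws <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.4)
  expect_equal(mpd(ws, star), 4)            # all pairs equal 2t
  expect_equal(mntd(ws, star), 4)

  rt <- generate_phylogeny(12, seed = 6)
  d <- patristic_matrix(rt)
  for (seed in 1:8) {
    sp <- sample(rt$tip.label, 5)
    w <- random_community(sp, seed)
    expect_equal(mpd(w, rt), bf_mpd(w, d), tolerance = 1e-12)
    expect_equal(mntd(w, rt), bf_mntd(w, d), tolerance = 1e-12)
    expect_equal(mpd(w, rt, abundance_weighted = FALSE),
                 bf_mpd(w, d, weighted = FALSE), tolerance = 1e-12)
    # equal weights reduce the weighted form to the unweighted mean
    eq <- stats::setNames(rep(1 / 5, 5), sp)
    expect_equal(mpd(eq, rt), mpd(eq, rt, abundance_weighted = FALSE),
                 tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(mpd(c(A = 1), tree))),
                 class = "undefined_metric")
})

test_that("weighted MPD relates to picante by the documented self-pair convention", {
  skip_if_not_installed("picante")
  rt <- generate_phylogeny(10, seed = 7)
  d <- ape::cophenetic.phylo(rt)
  set.seed(7)
  ab <- matrix(0, 1, 10, dimnames = list("p1", rt$tip.label))
  sp <- sample(10, 6)
  ab[1, sp] <- rlnorm(6)
  w <- ab[1, ab[1, ] > 0]
  a <- w / sum(w)
  # picante averages over all pairs including i = j (zero distances);
  # excluding self pairs rescales by 1 / (1 - sum(a^2))
  expect_equal(mpd(w, rt) * (1 - sum(a^2)),
               picante::mpd(ab, d, abundance.weighted = TRUE),
               tolerance = 1e-12)
  expect_equal(mntd(w, rt),
               picante::mntd(ab, d, abundance.weighted = TRUE),
               tolerance = 1e-12)
})

test_that("Faith's PD is root-inclusive, monotone and matches the edge-union oracle", {
  tree <- small_tree()
  expect_equal(faith_pd(setNames(rep(1, 4), tree$tip.label), tree),
               sum(tree$edge.length))
  expect_equal(faith_pd(c(A = 1), tree), 2)  # root-to-tip path
  rt <- generate_phylogeny(15, seed = 8)
  set.seed(8)
  a_sp <- sample(rt$tip.label, 4)
  b_sp <- union(a_sp, sample(rt$tip.label, 6))
  wa <- setNames(rep(1, length(a_sp)), a_sp)
  wb <- setNames(rep(1, length(b_sp)), b_sp)
  expect_lte(faith_pd(wa, rt), faith_pd(wb, rt))
  expect_equal(faith_pd(wa, rt), bf_pd(a_sp, rt), tolerance = 1e-12)
  expect_equal(faith_pd(wb, rt), bf_pd(b_sp, rt), tolerance = 1e-12)
})

test_that("phylo metrics are invariant to tip ordering and ladderization", {
  rt <- generate_phylogeny(10, seed = 9)
  rl <- ape::ladderize(rt)
  sp <- sample(rt$tip.label, 5)
  w <- random_community(sp, 2)
  expect_equal(mpd(w, rl), mpd(w, rt), tolerance = 1e-12)
  expect_equal(mntd(w, rl), mntd(w, rt), tolerance = 1e-12)
  expect_equal(faith_pd(w, rl), faith_pd(w, rt), tolerance = 1e-12)
})

test_that("frequency null preserves occurrence patterns and flags degenerate nulls", {
  rt <- generate_phylogeny(8, seed = 10)
  # identical abundances everywhere: every permutation is the observed
  # matrix, so the null sd is zero and ses is NA with a warning
  flat <- matrix(1, 4, 8, dimnames = list(paste0("p", 1:4), rt$tip.label))
  expect_warning(res <- frequency_null(flat, rt, n_iter = 99, seed = 1),
                 class = "degenerate_null")
  expect_true(all(is.na(res$ses_mpd)))

  set.seed(11)
  comm <- matrix(0, 5, 8, dimnames = list(paste0("p", 1:5), rt$tip.label))
  for (i in 1:5) comm[i, sample(8, 5)] <- rlnorm(5)
  res2 <- frequency_null(comm, rt, n_iter = 199, seed = 2)
  expect_equal(nrow(res2), 5)
  expect_true(all(is.finite(res2$ses_mpd)))
  res2b <- frequency_null(comm, rt, n_iter = 199, seed = 2)
  expect_identical(res2, res2b)
  expect_error(frequency_null(comm[1, , drop = FALSE], rt),
               class = "invalid_argument")
  expect_error(frequency_null(comm, rt, n_iter = 10), class = "invalid_argument")
})

test_that("exhaustive small communities match all brute-force oracles at once", {
  rt <- generate_phylogeny(8, seed = 12)
  d <- patristic_matrix(rt)
  subsets <- unlist(lapply(2:4, function(k)
    utils::combn(rt$tip.label, k, simplify = FALSE)), recursive = FALSE)
  for (i in seq_along(subsets)) {
    w <- random_community(subsets[[i]], i)
    expect_equal(mpd(w, rt), bf_mpd(w, d), tolerance = 1e-10)
    expect_equal(mntd(w, rt), bf_mntd(w, d), tolerance = 1e-10)
    expect_equal(faith_pd(w, rt), bf_pd(names(w), rt), tolerance = 1e-10)
  }
})
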