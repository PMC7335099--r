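# Independent brute-force oracles used to pin down the metric
# implementations.  These deliberately use naive enumeration (loops over
# pairs, explicit path walks, direct formula evaluation) rather than any
# code path from the package.

# patristic distance by explicit root-path walking on the edge table
bf_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (parent[node] != 0) {
      nodes <- c(nodes, node)
      node <- parent[node]
    }
    nodes
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    pi_ <- path_to_root(i)
    for (j in (i + 1):ntip) {
      pj <- path_to_root(j)
      shared <- intersect(pi_, pj)
      dij <- sum(elen[setdiff(pi_, shared)]) + sum(elen[setdiff(pj, shared)])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# weighted / unweighted MPD by explicit double loop
bf_mpd <- function(w, d, weighted = TRUE) {
  sp <- names(w)
  num <- 0; den <- 0
  for (i in sp) for (j in sp) {
    if (i == j) next
    wt <- if (weighted) w[[i]] * w[[j]] else 1
    num <- num + wt * d[i, j]
    den <- den + wt
  }
  num / den
}

# MNTD by per-species minimum scan
bf_mntd <- function(w, d, weighted = TRUE) {
  sp <- names(w)
  mins <- vapply(sp, function(i) min(d[i, setdiff(sp, i)]), numeric(1))
  if (weighted) sum(w / sum(w) * mins) else mean(mins)
}

# Faith PD by union of root-to-tip edge sets
bf_pd <- function(species, tree) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  elen <- numeric(length(parent))
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  edges <- integer(0)
  for (sp in match(species, tree$tip.label)) {
    node <- sp
    while (parent[node] != 0) {
      edges <- union(edges, node)
      node <- parent[node]
    }
  }
  sum(elen[edges])
}

# FDis by direct formula evaluation in standardized numeric trait space
bf_fdis <- function(traits, w) {
  x <- as.matrix(traits[names(w), , drop = FALSE])
  x <- scale(x)
  a <- w / sum(w)
  centroid <- colSums(a * x)
  z <- apply(x, 1, function(row) sqrt(sum((row - centroid)^2)))
  sum(a * z)
}

# Rao's Q by explicit double sum
bf_raoq <- function(w, d) {
  a <- w / sum(w)
  sp <- names(a)
  total <- 0
  for (i in sp) for (j in sp) total <- total + a[[i]] * a[[j]] * d[i, j]
  total
}

# month-by-month water-deficit bookkeeping, written as cumulative sums per
# hydrological year rather than the package's running recursion
bf_cwd <- function(balance, hydro) {
  out <- numeric(length(balance))
  for (h in unique(hydro)) {
    idx <- which(hydro == h)
    wd <- 0
    for (i in idx) {
      wd <- min(0, wd + balance[i])
      out[i] <- wd
    }
  }
  out
}

# fixed small ultrametric tree used across tests
small_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

random_community <- function(species, seed) {
  set.seed(seed)
  w <- stats::runif(length(species), 0.1, 1)
  stats::setNames(w / sum(w), species)
}
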