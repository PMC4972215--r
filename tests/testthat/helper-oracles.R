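# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately brute-force and separate from the package's
# own computational paths.

# Shared path length root -> MRCA(i, j), by explicit node-path intersection.
brute_force_vcv <- function(phy) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  edge_len <- function(child) phy$edge.length[phy$edge[, 2L] == child]
  path_edges <- function(tip) {
    nodes <- ape::nodepath(phy, root, tip)
    nodes[-1L]                       # child end of each edge on the path
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(vapply(shared, edge_len, numeric(1L)))
    }
  }
  V
}

# Felsenstein pruning for the BM log-likelihood at fixed (sigma2, z0):
# recursive, never forms the VCV.
pruning_bm_loglik <- function(phy, x, sigma2, z0) {
  phy <- ape::reorder.phylo(ape::multi2di(phy, random = FALSE), "postorder")
  n <- ape::Ntip(phy)
  x <- x[phy$tip.label]
  mu <- numeric(n + phy$Nnode)     # conditional mean per node
  extra <- numeric(n + phy$Nnode)  # extra variance accumulated at node
  mu[seq_len(n)] <- x
  lnL <- 0
  # postorder edge list: every parent appears after its descendants' edges
  for (parent in unique(phy$edge[, 1L])) {
    es <- which(phy$edge[, 1L] == parent)
    stopifnot(length(es) == 2L)
    c1 <- phy$edge[es[1L], 2L]; c2 <- phy$edge[es[2L], 2L]
    v1 <- phy$edge.length[es[1L]] + extra[c1]
    v2 <- phy$edge.length[es[2L]] + extra[c2]
    contrast <- mu[c1] - mu[c2]
    lnL <- lnL + dnorm(contrast, 0, sqrt(sigma2 * (v1 + v2)), log = TRUE)
    mu[parent] <- (v2 * mu[c1] + v1 * mu[c2]) / (v1 + v2)
    extra[parent] <- v1 * v2 / (v1 + v2)
  }
  root <- n + 1L
  lnL + dnorm(mu[root], z0, sqrt(sigma2 * extra[root]), log = TRUE)
}

# Exhaustive minimum-change count: enumerate every assignment of observed
# states to internal nodes (an optimal unit-cost labelling never needs an
# unobserved state).
exhaustive_parsimony <- function(phy, states) {
  states <- states[phy$tip.label]
  obs <- unique(states)
  if (length(obs) == 1L) return(0L)
  n <- ape::Ntip(phy)
  internal <- (n + 1L):(n + phy$Nnode)
  grid <- as.matrix(expand.grid(rep(list(obs), length(internal))))
  G <- nrow(grid)
  total <- numeric(G)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]
    b <- phy$edge[e, 2L]
    av <- if (a <= n) rep(states[a], G) else grid[, a - n]
    bv <- if (b <= n) rep(states[b], G) else grid[, b - n]
    total <- total + (av != bv)
  }
  as.integer(min(total))
}

# Deterministic small fixtures.
tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
star_tree <- function(n, len = 1) {
  labs <- paste0("t", seq_len(n))
  parse_newick(paste0("(", paste0(labs, ":", len, collapse = ","), ");"))
}

random_yule <- function(n, seed, lambda = 0.1) simulate_yule_tree(n, lambda, seed = seed)

# Two tips spanning an internal clade whose size falls in [lo, hi].
pick_clade_tips <- function(phy, lo, hi) {
  pp <- ape::prop.part(phy)
  sizes <- lengths(pp)
  idx <- which(sizes >= lo & sizes <= hi & sizes < ape::Ntip(phy))[1L]
  stopifnot(!is.na(idx))
  tips <- phy$tip.label[pp[[idx]]]
  tips[c(1L, length(tips))]
}
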