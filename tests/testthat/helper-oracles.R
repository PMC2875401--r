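# Shared fixtures and independent oracles used across the suite.

# random binary tree with branch lengths scaled to avoid K2P saturation
rand_tree <- function(n, bl_scale = 0.2) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length * bl_scale
  tr
}

# Brute-force Fitch oracle: minimum number of state changes over all
# internal-node labelings (vectorized over labelings).
bf_fitch_min <- function(tree, leaf_states, alphabet) {
  n <- length(tree$tip.label)
  k <- tree$Nnode
  lab_grid <- as.matrix(expand.grid(rep(list(alphabet), k),
                                    stringsAsFactors = FALSE))
  full <- matrix("", nrow = nrow(lab_grid), ncol = n + k)
  for (i in seq_len(n)) full[, i] <- leaf_states[[tree$tip.label[i]]]
  full[, n + seq_len(k)] <- lab_grid
  changes <- rep(0L, nrow(lab_grid))
  for (e in seq_len(nrow(tree$edge))) {
    changes <- changes +
      (full[, tree$edge[e, 1]] != full[, tree$edge[e, 2]])
  }
  min(changes)
}

# all 15 unrooted 5-leaf topologies (as unresolved Newick over fixed labels)
all_quintet_topologies <- function(labels) {
  stopifnot(length(labels) == 5)
  out <- list()
  # choose the cherry pair {i,j} and the second pair {k,l} among the rest:
  # every unrooted binary 5-leaf tree is ((i,j),(k,l),m)
  for (ij in utils::combn(5, 2, simplify = FALSE)) {
    rest <- setdiff(1:5, ij)
    for (kl in utils::combn(rest, 2, simplify = FALSE)) {
      m <- setdiff(rest, kl)
      nwk <- sprintf("((%s,%s),(%s,%s),%s);",
                     labels[ij[1]], labels[ij[2]],
                     labels[kl[1]], labels[kl[2]], labels[m])
      key <- paste(sort(lgtree::tree_bipartitions(ape::read.tree(text = nwk))),
                   collapse = ";")
      out[[key]] <- ape::read.tree(text = nwk)
    }
  }
  out
}

# least-squares fit of a distance matrix on a fixed topology; returns the
# residual sum of squares (0 iff the matrix is additive on that topology)
ls_residual <- function(topology, d) {
  labs <- topology$tip.label
  n <- length(labs)
  pairs <- utils::combn(n, 2)
  topo <- ape::unroot(topology)
  topo$edge.length <- rep(1, nrow(topo$edge))
  nn <- n + topo$Nnode
  # indicator: does edge e lie on the path between pair p?
  A <- matrix(0, ncol(pairs), nrow(topo$edge))
  for (e in seq_len(nrow(topo$edge))) {
    child <- topo$edge[e, 2]
    side <- lgtree::node_leaves(topo, child)
    in_side <- matrix(labs[pairs] %in% side, nrow = 2)
    A[, e] <- xor(in_side[1, ], in_side[2, ])
  }
  dvec <- d[cbind(labs[pairs[1, ]], labs[pairs[2, ]])]
  fit <- qr(A)
  resid <- dvec - A %*% qr.coef(fit, dvec)
  sum(resid^2)
}

# scan-all-edges midpoint oracle: smallest achievable maximum root-to-leaf
# distance over every possible root position on every edge
min_max_root_leaf <- function(tree) {
  n <- length(tree$tip.label)
  dn <- ape::dist.nodes(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    da <- dn[a, seq_len(n)]; db <- dn[b, seq_len(n)]
    # a leaf is reached via a iff da < db; for a root t from a the eccentric
    # leaf distance is max(maxA + t, maxB + len - t), minimized in closed form
    maxA <- max(da[da <= db])
    maxB <- if (any(db < da)) max(db[db < da]) else -Inf
    t_star <- min(max((maxB + len - maxA) / 2, 0), len)
    best <- min(best, max(maxA + t_star, maxB + len - t_star))
  }
  best
}

# independent K2P arrangement (log1p decomposition)
k2p_reference <- function(P, Q) {
  -0.5 * log1p(-(2 * P + Q)) - 0.25 * log1p(-2 * Q)
}

# simple five-taxon group map used in classifier tests
toy_groups <- function() {
  taxon_group_map(
    c("Q", "X1", "X2", "IV1", "IV2", "O1"),
    group = c("cluster_IV", "cluster_XIVa", "cluster_XIVa",
              "cluster_IV", "cluster_IV", "other"))
}
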