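test_that("K2P distance matches its closed form and flags saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)

  # 100 sites, 10 transitions, no transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)

  # P = Q = 0.25 is inside the domain (no spurious saturation)
  expect_equal(k2p_from_pq(0.25, 0.25), -0.5 * log(0.25 * sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(k2p_from_pq(0.25, 0.25), 0.8664, tolerance = 1e-4)

  expect_error(k2p_from_pq(0.4, 0.2), class = "lgtree_saturation_error")
  expect_error(k2p_from_pq(0.1, 0.5), class = "lgtree_saturation_error")
  expect_error(k2p_distance("---A", "A---"),
               class = "lgtree_undefined_distance")
})

test_that("gap/ambiguity sites are pairwise-deleted; complete deletion flag", {
  # gap columns only affect pairs that include them under pairwise deletion
  aln <- c(s1 = "AAAAAAAAAA", s2 = "GAAAAAAAA-", s3 = "AAAAAAAAAA")
  d_pair <- k2p_matrix(aln)
  # s1 vs s2: 9 compared sites, 1 transition
  expect_equal(d_pair["s1", "s2"], k2p_from_pq(1 / 9, 0), tolerance = 1e-12)
  expect_equal(d_pair["s1", "s3"], 0)
  d_comp <- k2p_matrix(aln, deletion = "complete")
  expect_equal(d_comp["s1", "s2"], k2p_from_pq(1 / 9, 0), tolerance = 1e-12)
})

test_that("K2P is strictly increasing in P for fixed Q", {
  for (Q in c(0, 0.05, 0.2)) {
    P <- seq(0, (1 - Q) / 2 - 0.02, length.out = 25)
    d <- vapply(P, k2p_from_pq, 0, Q = Q)
    expect_true(all(diff(d) > 0))
  }
})

test_that("NJ solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # a = (d12+d13-d23)/2 = 3, b = 2, c = 6
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 3, B = 2, C = 6))
})

test_that("NJ recovers topology and path lengths on additive matrices", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    t0 <- rand_tree(n, bl_scale = 1)
    d <- ape::cophenetic.phylo(t0)
    tr <- neighbor_joining(d)
    expect_identical(tree_bipartitions(tr), tree_bipartitions(t0))
    d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(d2 - d)), 1e-9)
  }
})

test_that("NJ agrees with brute-force least squares on 5-taxon matrices", {
  set.seed(11)
  labs <- letters[1:5]
  topos <- all_quintet_topologies(labs)
  expect_length(topos, 15)
  for (i in 1:20) {
    t0 <- ape::rtree(5)
    t0$tip.label <- sample(labs)
    d <- ape::cophenetic.phylo(t0)[labs, labs]
    res <- vapply(topos, ls_residual, 0, d = d)
    best <- topos[[which.min(res)]]
    tr <- neighbor_joining(d)
    expect_identical(tree_bipartitions(tr), tree_bipartitions(best))
  }
})

test_that("NJ is invariant to taxon input order and rejects bad input", {
  set.seed(3)
  t0 <- rand_tree(8, bl_scale = 1)
  d <- ape::cophenetic.phylo(t0)
  perm <- sample(rownames(d))
  tr1 <- neighbor_joining(d)
  tr2 <- neighbor_joining(d[perm, perm])
  expect_identical(tree_bipartitions(tr1), tree_bipartitions(tr2))

  expect_error(neighbor_joining(matrix(0, 2, 2)), class = "lgtree_arg_error")
  dbad <- d
  dbad[1, 2] <- NaN
  expect_error(neighbor_joining(dbad), class = "lgtree_arg_error")
})

test_that("bootstrap supports behave at the edges and are deterministic", {
  # two identical clades of duplicated sequences: separating split gets 100
  set.seed(2)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  other <- base
  other[1:30] <- chartr("ACGT", "GTAC", base[1:30])  # 15% divergence
  aln <- rbind(A1 = base, A2 = base, B1 = other, B2 = other)
  tr <- bootstrap_support(aln, replicates = 100, seed = 1)
  s <- node_supports(tr)
  expect_equal(s[!is.na(s)], 100)

  # one replicate: all supports 0 or 100
  t0 <- rand_tree(6)
  aln2 <- evolve_alignment(t0, n_sites = 400, seed = 5)
  tr1 <- bootstrap_support(aln2, replicates = 1, seed = 2)
  s1 <- node_supports(tr1)
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  # same seed, same supports
  trA <- bootstrap_support(aln2, replicates = 50, seed = 42)
  trB <- bootstrap_support(aln2, replicates = 50, seed = 42)
  expect_identical(node_supports(trA), node_supports(trB))

  expect_error(bootstrap_support(aln2[, 0], replicates = 10),
               class = "lgtree_arg_error")
  expect_error(bootstrap_support(aln2[1:3, ], replicates = 10),
               class = "lgtree_arg_error")
})

test_that("bootstrap supports grow with replicates under strong signal", {
  t0 <- read_newick("((A:0.05,B:0.05):0.1,(C:0.05,D:0.05):0.1,(E:0.05,F:0.05):0.1);")
  aln <- evolve_alignment(t0, n_sites = 2000, seed = 8)
  s10 <- node_supports(bootstrap_support(aln, replicates = 10, seed = 3))
  s200 <- node_supports(bootstrap_support(aln, replicates = 200, seed = 3))
  ok <- !is.na(s10) & !is.na(s200)
  expect_true(all(s200[ok] >= s10[ok] - 5))
  expect_true(mean(s200[ok]) > 90)
})

test_that("outgroup rooting places the root on the outgroup edge", {
  tr <- read_newick("((A:1,B:1)90:1,C:1);")
  r <- root_tree(tr, "outgroup", outgroup = "C")
  expect_true(ape::is.rooted(r))
  root_children <- r$edge[r$edge[, 1] == length(r$tip.label) + 1, 2]
  expect_true(match("C", r$tip.label) %in% root_children)
  expect_identical(tree_bipartitions(r), tree_bipartitions(tr))
  expect_error(root_tree(tr, "outgroup", outgroup = "Z"),
               class = "lgtree_arg_error")
})

test_that("midpoint rooting: closed form and all-edge scan oracle", {
  r <- midpoint_root(read_newick("(A:1,B:3);"))
  n <- length(r$tip.label)
  dr <- ape::dist.nodes(r)[n + 1, seq_len(n)]
  expect_equal(unname(dr), c(2, 2))

  set.seed(9)
  for (i in 1:30) {
    t0 <- rand_tree(sample(4:15, 1), bl_scale = 1)
    r <- midpoint_root(t0)
    nn <- length(r$tip.label)
    achieved <- max(ape::dist.nodes(r)[nn + 1, seq_len(nn)])
    expect_equal(achieved, min_max_root_leaf(t0), tolerance = 1e-9)
    expect_identical(tree_bipartitions(r), tree_bipartitions(t0))
  }
})

test_that("rooting preserves support-to-clade attachment", {
  tr <- read_newick("(((A:1,B:1)88:1,C:1)75:1,(D:1,E:1)60:2);")
  r <- midpoint_root(tr)
  # the {A,B} clade must still carry 88 wherever it ends up
  n <- length(r$tip.label)
  parts <- ape::prop.part(r)
  s <- node_supports(r)
  key <- vapply(seq_along(parts), function(k)
    paste(sort(r$tip.label[parts[[k]]]), collapse = "|"), "")
  expect_equal(unname(s[key == "A|B"]), 88)
  expect_equal(unname(s[key == "D|E"]), 60)
})
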