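toy_cfg <- classifier_config()

test_that("the novelty gate is strict and bypasses the tree", {
  gm <- toy_groups()
  tr <- read_newick("(((Q:1,X1:1)95:1,X2:1)90:1,(IV1:1,IV2:1)99:1);")
  call <- classify_gene(tr, "Q", gm, top_evalue = 1e-3, cfg = toy_cfg)
  expect_equal(call$status, "novel")
  expect_true(is.na(call$decision_support))
  expect_length(call$decision_groups, 0)

  # boundary: e-value exactly at the threshold is NOT novel (strict >)
  call2 <- classify_gene(tr, "Q", gm, top_evalue = 1e-6, cfg = toy_cfg)
  expect_false(call2$status == "novel")
})

test_that("tree walk yields no_lgt / lgt / unresolved per decision-node groups", {
  gm <- toy_groups()

  # all non-query leaves focal -> no_lgt
  t_no <- read_newick("((Q:1,IV1:1)98:1,(IV2:1,IV1b:1)99:1);")
  gm_no <- taxon_group_map(c("Q", "IV1", "IV2", "IV1b"),
                           group = rep("cluster_IV", 4))
  call <- classify_gene(t_no, "Q", gm_no, 1e-20, toy_cfg)
  expect_equal(call$status, "no_lgt")
  expect_equal(call$decision_support, 98)

  # query nested in a supported all-XIVa clade -> lgt
  t_lgt <- read_newick("(((Q:1,X1:1)95:1,X2:1)90:1,(IV1:1,IV2:1)99:1);")
  call <- classify_gene(t_lgt, "Q", gm, 1e-20, toy_cfg)
  expect_equal(call$status, "lgt")
  expect_equal(call$decision_groups, "cluster_XIVa")
  expect_equal(call$decision_support, 95)

  # inner support below gate, next supported node mixed -> unresolved
  t_mix <- read_newick("(((Q:1,X1:1)55:1,IV1:1)80:1,(X2:1,IV2:1)99:1);")
  call <- classify_gene(t_mix, "Q", gm, 1e-20, toy_cfg)
  expect_equal(call$status, "unresolved")
  expect_equal(call$decision_support, 80)
  expect_setequal(call$decision_groups, c("cluster_IV", "cluster_XIVa"))

  # no gate-passing node anywhere -> unresolved with absent fields
  t_none <- read_newick("(((Q:1,X1:1)55:1,X2:1)50:1,(IV1:1,IV2:1)40:1);")
  call <- classify_gene(t_none, "Q", gm, 1e-20, toy_cfg)
  expect_equal(call$status, "unresolved")
  expect_true(is.na(call$decision_support))

  expect_error(classify_gene(t_lgt, "NOPE", gm, 1e-20, toy_cfg),
               class = "lgtree_arg_error")
})

test_that("the decision-node walk matches exhaustive enumeration on a 5-leaf tree", {
  gm <- toy_groups()
  tr <- read_newick("(((Q:1,X1:1)95:1,X2:1)90:1,IV1:1,IV2:1);")
  tr <- root_tree(tr, "outgroup", outgroup = "IV2")
  # oracle: enumerate root-path nodes, their supports and group sets
  call <- classify_gene(tr, "Q", gm, 1e-20, toy_cfg)
  path_nodes <- list(c("X1"), c("X1", "X2"))  # parent, grandparent (post-root)
  sup <- c(95, 90)
  first <- which(sup > 60)[1]
  expected_groups <- sort(unique(gm$entries$group[
    match(path_nodes[[first]], gm$entries$taxon)]))
  expect_equal(call$decision_groups, expected_groups)
  expect_equal(call$status, "lgt")
})

test_that("unsupported nodes are walked past, even when they contain other species", {
  gm <- toy_groups()
  # parent has other species but support below the gate: keep walking
  tr <- read_newick("(((Q:1,X1:1)42:1,IV1:1)85:1,(X2:1,IV2:1)99:1);")
  call <- classify_gene(tr, "Q", gm, 1e-20, toy_cfg)
  expect_equal(call$decision_support, 85)
  expect_equal(call$status, "unresolved")
})

test_that("Fitch two-pass reconstruction matches the worked examples", {
  t4 <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")

  f0 <- fitch_states(t4, c(a = "IV", b = "IV", c = "IV", d = "IV"))
  expect_equal(f0$changes, 0)
  expect_true(all(vapply(f0$sets, identical, TRUE, "IV")))

  f1 <- fitch_states(t4, c(a = "IV", b = "XIVa", c = "XIVa", d = "XIVa"))
  expect_equal(f1$changes, 1)
  expect_equal(f1$sets[[5]], "XIVa")  # root = node 5

  f2 <- fitch_states(t4, c(a = "IV", b = "XIVa", c = "IV", d = "XIVa"))
  expect_equal(f2$changes, 2)
  expect_setequal(f2$sets[[5]], c("IV", "XIVa"))
  expect_setequal(f2$final[[5]], c("IV", "XIVa"))  # ambiguity retained

  expect_error(fitch_states(t4, c(a = "IV", b = "IV", c = "IV")),
               class = "lgtree_arg_error")
})

test_that("Fitch change count equals the brute-force minimum (sampled)", {
  set.seed(13)
  alphabet <- c("cluster_IV", "cluster_XIVa", "other")
  for (i in 1:150) {
    n <- sample(3:8, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(alphabet, n, replace = TRUE), tr$tip.label)
    f <- fitch_states(tr, states)
    expect_equal(f$changes, bf_fitch_min(tr, states, alphabet))
  }
})

test_that("direction inference follows the singleton rules", {
  gm <- toy_groups()
  cfg <- toy_cfg

  # pure XIVa decision clade with >= 2 donor leaves: resolved direction
  tr <- read_newick("(((Q:1,X1:1)95:1,X2:1)90:1,(IV1:1,IV2:1)99:1);")
  call <- classify_and_infer(tr, "Q", gm, 1e-20, cfg)
  expect_equal(call$status, "lgt")
  expect_equal(call$donor, "cluster_XIVa")
  expect_equal(call$direction, "from_cluster_XIVa_to_cluster_IV")

  # mixed non-focal decision groups {XIVa, other}: lgt, direction unresolved
  tr2 <- read_newick("(((Q:1,X1:1)40:1,O1:1)95:1,(IV1:1,IV2:1)99:1);")
  call2 <- classify_and_infer(tr2, "Q", gm, 1e-20, cfg)
  expect_equal(call2$status, "lgt")
  expect_setequal(call2$decision_groups, c("cluster_XIVa", "other"))
  expect_equal(call2$direction, "unresolved")
  expect_true(is.na(call2$donor))

  # contract error on a non-lgt call
  no_call <- lgt_call("g", "no_lgt")
  dummy_fitch <- fitch_states(read_newick("((X1:1,X2:1):1,O1:1);"),
                              c(X1 = "cluster_XIVa", X2 = "cluster_XIVa",
                                O1 = "other"))
  expect_error(infer_direction(no_call, dummy_fitch, "Q", cfg),
               class = "lgtree_contract_error")
})

test_that("classification is invariant to child rotation and re-serialization", {
  gm <- toy_groups()
  tr <- read_newick("(((Q:1,X1:1)95:1,X2:1)90:1,(IV1:1,IV2:1)99:1);")
  base <- classify_and_infer(tr, "Q", gm, 1e-20, toy_cfg)

  rt <- read_newick(write_newick(tr))
  rot <- ape::rotate(tr, node = length(tr$tip.label) + 1)
  for (variant in list(rt, rot)) {
    v <- classify_and_infer(variant, "Q", gm, 1e-20, toy_cfg)
    expect_equal(v$status, base$status)
    expect_equal(v$decision_groups, base$decision_groups)
    expect_equal(v$direction, base$direction)
  }
})

test_that("all-focal trees never produce lgt (property)", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- c("Q", sprintf("IV_%d", seq_len(n - 1)))
    tr <- set_node_supports(tr, c(NA, runif(tr$Nnode - 1, 0, 100)))
    gm <- taxon_group_map(tr$tip.label,
                          group = rep("cluster_IV", n))
    call <- classify_gene(tr, "Q", gm, 1e-20, toy_cfg)
    expect_true(call$status %in% c("no_lgt", "unresolved"))
  }
})

test_that("reconciliation is conservative, commutative, and flags discordance", {
  mk <- function(status, support = NA_real_, direction = "not_applicable") {
    lgt_call("g1", status, decision_support = support,
             direction = direction,
             decision_groups = if (status == "lgt") "cluster_XIVa"
             else character(0),
             donor = if (status == "lgt" && grepl("^from", direction))
               "cluster_XIVa" else NA_character_,
             low_support = !is.na(support) && support < 70)
  }
  expect_equal(reconcile_methods(mk("lgt", 95), mk("lgt", 95))$status, "lgt")
  expect_equal(reconcile_methods(mk("unresolved"), mk("no_lgt"))$status,
               "no_lgt")

  # low-support NJ lgt overruled by ML no_lgt, flagged
  rec <- reconcile_methods(mk("lgt", 61), mk("no_lgt"))
  expect_equal(rec$status, "no_lgt")
  expect_true(rec$low_support)
  expect_true(rec$discordant)

  # NJ unresolved + ML lgt stays out of the conservative lgt count
  expect_equal(reconcile_methods(mk("unresolved"), mk("lgt", 90))$status,
               "unresolved")

  statuses <- c("novel", "no_lgt", "unresolved", "lgt")
  for (a in statuses) for (b in statuses) {
    expect_equal(reconcile_methods(mk(a, 90), mk(b, 90))$status,
                 reconcile_methods(mk(b, 90), mk(a, 90))$status)
  }

  expect_error(reconcile_methods(lgt_call("g1", "no_lgt"),
                                 lgt_call("g2", "no_lgt")),
               class = "lgtree_arg_error")
})

test_that("summaries count statuses, directions, and donors", {
  expect_equal(summarize_calls(list())$total, 0)
  calls <- list(
    lgt_call("a", "lgt", donor = "cluster_XIVa",
             direction = "from_cluster_XIVa_to_cluster_IV"),
    lgt_call("b", "lgt", direction = "unresolved"),
    lgt_call("c", "no_lgt"),
    lgt_call("d", "novel"))
  s <- summarize_calls(calls)
  expect_equal(s$lgt, 2)
  expect_equal(s$direction_resolved, 1)
  expect_equal(unname(s$per_donor["cluster_XIVa"]), 1)
  expect_equal(s$no_lgt, 1)
  expect_equal(s$novel, 1)
})
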