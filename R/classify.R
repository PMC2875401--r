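#' LGT call record
#'
#' @param gene_id Gene identifier.
#' @param status One of `"novel"`, `"no_lgt"`, `"unresolved"`, `"lgt"`.
#' @param query Query leaf label.
#' @param decision_support Support of the decision node, or `NA`.
#' @param decision_groups Group labels of the decision node's non-query leaf
#'   descendants.
#' @param decision_leaves Non-query leaf labels under the decision node.
#' @param donor Donor group label or `NA`.
#' @param direction `"from_<donor>_to_<focal>"`, `"unresolved"`, or
#'   `"not_applicable"`.
#' @param method Tree method tag: `"nj"`, `"ml"`, `"reconciled"`, `"other"`.
#' @param low_support Logical report-only flag.
#' @return An object of class `lgt_call`.
#' @export
lgt_call <- function(gene_id, status, query = NA_character_,
                     decision_support = NA_real_,
                     decision_groups = character(0),
                     decision_leaves = character(0),
                     donor = NA_character_,
                     direction = "not_applicable",
                     method = "other",
                     low_support = FALSE) {
  status <- match.arg(status, c("novel", "no_lgt", "unresolved", "lgt"))
  if (!is.na(donor) && status != "lgt")
    abort_lgtree("donor group can only accompany status 'lgt'",
                 "lgtree_contract_error")
  structure(
    list(gene_id = gene_id, status = status, query = query,
         decision_support = decision_support,
         decision_groups = decision_groups,
         decision_leaves = decision_leaves,
         donor = donor, direction = direction, method = method,
         low_support = low_support),
    class = "lgt_call")
}

#' @export
print.lgt_call <- function(x, ...) {
  cat(sprintf("lgt_call [%s] %s: %s", x$method, x$gene_id, x$status))
  if (!is.na(x$decision_support))
    cat(sprintf(" (decision support %.4g, groups {%s})",
                x$decision_support, paste(x$decision_groups, collapse = ",")))
  if (x$status == "lgt") cat(sprintf(", direction %s", x$direction))
  if (isTRUE(x$low_support)) cat(" [low support]")
  cat("\n")
  invisible(x)
}

#' Classify a gene as novel / no-LGT / unresolved / LGT by a bootstrap-gated
#' tree walk
#'
#' If the gene's best reference-database e-value exceeds the novelty
#' threshold the gene is `"novel"` and the tree is not consulted. Otherwise
#' the walk starts at the query leaf's parent and steps toward the root; the
#' *decision node* is the first node whose support is strictly greater than
#' the support threshold and whose leaf descendants include at least one
#' sequence from a species different from the query's. The groups `G` of the
#' decision node's non-query leaf descendants determine the call: only the
#' focal group gives `"no_lgt"`, focal mixed with non-focal gives
#' `"unresolved"`, and only non-focal groups give `"lgt"`. If no node on the
#' root path passes the gate the gene is `"unresolved"` with decision fields
#' absent. Nodes with absent support never satisfy the gate; the walk
#' continues past unsupported nodes.
#'
#' @param tree Rooted `phylo` with supports as node labels (unrooted trees
#'   are rooted by the config's policy first).
#' @param query Query leaf label.
#' @param groups A [taxon_group_map()] resolving every non-query leaf.
#' @param top_evalue E-value of the gene's best reference hit.
#' @param cfg A [classifier_config()].
#' @param gene_id Gene identifier (defaults to `query`).
#' @param method Tree method tag stored on the call.
#' @return An [lgt_call()].
#' @export
classify_gene <- function(tree, query, groups, top_evalue,
                          cfg = classifier_config(), gene_id = query,
                          method = "nj") {
  if (!(query %in% tree$tip.label))
    abort_lgtree(sprintf("query leaf '%s' not found in tree", query),
                 "lgtree_arg_error")
  if (top_evalue > cfg$evalue_threshold)
    return(lgt_call(gene_id, "novel", query = query, method = method))

  if (!ape::is.rooted(tree))
    tree <- root_tree(tree, cfg$rooting, outgroup = cfg$outgroup)

  n <- length(tree$tip.label)
  supports <- node_supports(tree)
  qtip <- match(query, tree$tip.label)
  qspecies <- tryCatch(species_of(groups, query), lgtree_error = function(e) query)

  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p)) p else NA_integer_
  }

  node <- parent_of(qtip)
  while (!is.na(node)) {
    s <- supports[node - n]
    if (!is.na(s) && s > cfg$support_threshold) {
      desc <- setdiff(node_leaves(tree, node), query)
      if (any(species_of(groups, desc) != qspecies)) {
        g <- sort(unique(group_of(groups, desc)))
        focal <- cfg$focal_group
        status <-
          if (all(g == focal)) "no_lgt"
          else if (focal %in% g) "unresolved"
          else "lgt"
        return(lgt_call(
          gene_id, status, query = query,
          decision_support = s, decision_groups = g, decision_leaves = desc,
          direction = if (status == "lgt") "unresolved" else "not_applicable",
          method = method, low_support = s < cfg$low_support_flag))
      }
    }
    node <- parent_of(node)
  }
  lgt_call(gene_id, "unresolved", query = query, method = method)
}

#' Fitch parsimony ancestral-state reconstruction
#'
#' Two-pass algorithm on a rooted tree over an arbitrary finite state
#' alphabet. The bottom-up pass assigns each internal node the intersection
#' of its child state sets when non-empty, else their union (incrementing
#' the change count); the top-down pass computes final state sets, retaining
#' the full ambiguity set rather than sampling a state. The change count is
#' the parsimony minimum for binary trees.
#'
#' @param tree Rooted `phylo`.
#' @param leaf_groups Named character vector: leaf label -> state (group
#'   label). Every leaf must be labelled.
#' @return An object of class `fitch_result`: `tree`, `sets` (bottom-up
#'   state sets per node, indexed 1..Ntip+Nnode), `final` (top-down sets),
#'   and `changes`.
#' @export
fitch_states <- function(tree, leaf_groups) {
  n <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(leaf_groups))
  if (length(missing))
    abort_lgtree(paste0("unlabeled leaves: ", paste(missing, collapse = ", ")),
                 "lgtree_arg_error")
  if (!ape::is.rooted(tree))
    abort_lgtree("fitch_states needs a rooted tree", "lgtree_arg_error")

  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- leaf_groups[[tree$tip.label[i]]]

  # process internal nodes deepest-first so children are resolved before
  # their parent (robust to any edge ordering in the phylo object)
  root <- n + 1L
  depth <- rep(NA_integer_, nn)
  depth[root] <- 0L
  repeat {
    todo <- !is.na(depth[tree$edge[, 1]]) & is.na(depth[tree$edge[, 2]])
    if (!any(todo)) break
    depth[tree$edge[todo, 2]] <- depth[tree$edge[todo, 1]] + 1L
  }
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  internal <- (n + 1L):nn
  changes <- 0L
  for (p in internal[order(depth[internal], decreasing = TRUE)]) {
    kids <- kids_of[[as.character(p)]]
    acc <- sets[[kids[1]]]
    for (k in kids[-1]) {
      inter <- intersect(acc, sets[[k]])
      if (length(inter)) {
        acc <- inter
      } else {
        acc <- union(acc, sets[[k]])
        changes <- changes + 1L
      }
    }
    sets[[p]] <- sort(acc)
  }

  final <- vector("list", nn)
  final[[root]] <- sets[[root]]
  ord <- order(depth[tree$edge[, 2]])  # shallow edges first: parents ready
  for (k in ord) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    inherited <- intersect(final[[p]], sets[[ch]])
    final[[ch]] <- if (length(inherited)) sort(inherited) else sets[[ch]]
  }

  structure(list(tree = tree, sets = sets, final = final, changes = changes),
            class = "fitch_result")
}

#' Infer donor group and transfer direction for an LGT call
#'
#' The donor is read off the Fitch bottom-up state set of the decision node:
#' direction is reported as `from_<donor>_to_<focal>` only when that set is
#' a singleton not containing the focal group *and* the decision node's
#' descendant groups form a singleton. Any ambiguity leaves the direction
#' `"unresolved"`. The Fitch reconstruction is computed on the tree with the
#' query leaf removed, so the query's own (focal) label does not vote on the
#' ancestral state of the clade it inserted into.
#'
#' @param call An [lgt_call()] with status `"lgt"` (contract error
#'   otherwise).
#' @param fitch A [fitch_states()] result on the query-dropped tree.
#' @param query Query leaf label.
#' @param cfg A [classifier_config()].
#' @return The call with `donor` and `direction` filled.
#' @export
infer_direction <- function(call, fitch, query, cfg = classifier_config()) {
  if (call$status != "lgt")
    abort_lgtree("infer_direction requires an 'lgt' call",
                 "lgtree_contract_error")
  desc <- setdiff(call$decision_leaves, query)
  ptree <- fitch$tree
  if (query %in% ptree$tip.label)
    abort_lgtree("fitch result must be computed on the query-dropped tree",
                 "lgtree_contract_error")
  node_set <-
    if (length(desc) == 1) {
      fitch$sets[[match(desc, ptree$tip.label)]]
    } else {
      fitch$sets[[ape::getMRCA(ptree, desc)]]
    }
  ok <- length(node_set) == 1 &&
    !(cfg$focal_group %in% node_set) &&
    length(call$decision_groups) == 1
  if (ok) {
    call$donor <- node_set
    call$direction <- sprintf("from_%s_to_%s", node_set, cfg$focal_group)
  } else {
    call$direction <- "unresolved"
  }
  call
}

#' Classify a gene and, for LGT calls, infer the transfer direction
#'
#' Convenience wrapper combining [classify_gene()], [fitch_states()] on the
#' query-dropped tree, and [infer_direction()].
#'
#' @inheritParams classify_gene
#' @return An [lgt_call()].
#' @export
classify_and_infer <- function(tree, query, groups, top_evalue,
                               cfg = classifier_config(), gene_id = query,
                               method = "nj") {
  call <- classify_gene(tree, query, groups, top_evalue, cfg,
                        gene_id = gene_id, method = method)
  if (call$status != "lgt") return(call)
  if (!ape::is.rooted(tree))
    tree <- root_tree(tree, cfg$rooting, outgroup = cfg$outgroup)
  ptree <- ape::drop.tip(tree, query)
  lg <- setNames(group_of(groups, ptree$tip.label), ptree$tip.label)
  infer_direction(call, fitch_states(ptree, lg), query, cfg)
}

reconcile_status <- function(a, b) {
  if (a == b) return(a)
  if ("no_lgt" %in% c(a, b)) return("no_lgt")
  "unresolved"
}

#' Reconcile NJ- and ML-based calls for one gene
#'
#' Default `"conservative"` policy: the reconciled status is `lgt` only when
#' both methods call `lgt`; a `no_lgt` from either method wins over `lgt` or
#' `unresolved`; all other disagreements reconcile to `unresolved`. The
#' policy is commutative in its two arguments. Discordant genes are flagged
#' and both per-method calls are retained on the result.
#'
#' @param nj_call,ml_call [lgt_call()]s for the same gene.
#' @param policy Reconciliation policy (only `"conservative"`).
#' @return An [lgt_call()] with `method = "reconciled"`, plus fields
#'   `discordant`, `nj`, `ml`.
#' @export
reconcile_methods <- function(nj_call, ml_call, policy = "conservative") {
  policy <- match.arg(policy, "conservative")
  if (!identical(nj_call$gene_id, ml_call$gene_id))
    abort_lgtree(sprintf("gene-id mismatch: '%s' vs '%s'",
                         nj_call$gene_id, ml_call$gene_id),
                 "lgtree_arg_error")
  status <- reconcile_status(nj_call$status, ml_call$status)
  direction <- "not_applicable"
  donor <- NA_character_
  if (status == "lgt") {
    direction <- if (identical(nj_call$direction, ml_call$direction))
      nj_call$direction else "unresolved"
    if (identical(nj_call$donor, ml_call$donor)) donor <- nj_call$donor
    if (direction == "unresolved") donor <- NA_character_
  }
  out <- lgt_call(
    nj_call$gene_id, status, query = nj_call$query,
    decision_support = nj_call$decision_support,
    decision_groups = union(nj_call$decision_groups, ml_call$decision_groups),
    decision_leaves = union(nj_call$decision_leaves, ml_call$decision_leaves),
    donor = donor, direction = direction, method = "reconciled",
    low_support = isTRUE(nj_call$low_support) || isTRUE(ml_call$low_support))
  out$discordant <- nj_call$status != ml_call$status
  out$nj <- nj_call
  out$ml <- ml_call
  out
}

#' Summarize a set of LGT calls
#'
#' @param calls List of [lgt_call()]s (any mix of methods; reconciled calls
#'   contribute their NJ/ML children to the discordance count).
#' @return A list of counts: `total`, per-status counts, `lgt`,
#'   `direction_resolved`, `per_donor` (named integer vector), and
#'   `discordant`.
#' @export
summarize_calls <- function(calls) {
  if (!length(calls))
    return(list(total = 0L, novel = 0L, no_lgt = 0L, unresolved = 0L,
                lgt = 0L, direction_resolved = 0L,
                per_donor = integer(0), discordant = 0L))
  status <- vapply(calls, `[[`, "", "status")
  direction <- vapply(calls, `[[`, "", "direction")
  donors <- vapply(calls, function(x) x$donor %||% NA_character_, "")
  resolved <- status == "lgt" & grepl("^from_", direction)
  list(
    total = length(calls),
    novel = sum(status == "novel"),
    no_lgt = sum(status == "no_lgt"),
    unresolved = sum(status == "unresolved"),
    lgt = sum(status == "lgt"),
    direction_resolved = sum(resolved),
    per_donor = table(donors[resolved & !is.na(donors)]) |> c(),
    discordant = sum(vapply(calls, function(x) isTRUE(x$discordant), TRUE)))
}
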