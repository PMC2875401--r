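# Adjacency view of a phylo object: neighbor lists plus per-edge length and
# support (the node label of whichever endpoint is the child). Supports are
# properties of edges/splits, so they must travel with the edge when the tree
# is rerooted.
.tree_adjacency <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  nb <- vector("list", nn)
  elen <- new.env(parent = emptyenv())
  esup <- new.env(parent = emptyenv())
  key <- function(a, b) paste(min(a, b), max(a, b))
  lab <- tree$node.label
  has_len <- !is.null(tree$edge.length)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    nb[[p]] <- c(nb[[p]], ch)
    nb[[ch]] <- c(nb[[ch]], p)
    assign(key(p, ch), if (has_len) tree$edge.length[k] else NA_real_,
           envir = elen)
    if (ch > n && !is.null(lab) && nzchar(lab[ch - n]))
      assign(key(p, ch), lab[ch - n], envir = esup)
  }
  list(nb = nb, n = n,
       elen = function(a, b) get(key(a, b), envir = elen),
       esup = function(a, b) get0(key(a, b), envir = esup) %||% "",
       has_len = has_len)
}

# Reroot `tree` on the edge {a, b}, placing the root `t` from `a`.
# Unary nodes created by removing an old degree-2 root are spliced out.
.reroot_at_edge <- function(tree, a, b, t = NULL) {
  adj <- .tree_adjacency(tree)
  fmt <- function(x) sprintf("%.15g", x)
  lenstr <- function(x) if (adj$has_len) paste0(":", fmt(x)) else ""

  sub <- function(x, from) {
    if (x <= adj$n)
      return(list(core = tree$tip.label[x], add = 0))
    kids <- setdiff(adj$nb[[x]], from)
    if (length(kids) == 1) {
      r <- sub(kids, x)
      return(list(core = r$core,
                  add = r$add + (if (adj$has_len) adj$elen(x, kids) else 0)))
    }
    parts <- vapply(kids, function(y) {
      r <- sub(y, x)
      paste0(r$core, lenstr(adj$elen(x, y) + r$add))
    }, "")
    list(core = paste0("(", paste(parts, collapse = ","), ")",
                       adj$esup(x, from)),
         add = 0)
  }

  ra <- sub(a, b)
  rb <- sub(b, a)
  lab <- adj$elen(a, b)
  if (is.null(t)) t <- if (adj$has_len) lab / 2 else NA_real_
  newick <- paste0("(", ra$core, lenstr(t + ra$add), ",",
                   rb$core, lenstr(lab - t + rb$add), ");")
  ape::read.tree(text = newick)
}

#' Root a gene tree
#'
#' @param tree A `phylo` object.
#' @param policy `"midpoint"` (root at the halfway point of the longest
#'   leaf-to-leaf path), `"outgroup"` (root on the pendant edge of the named
#'   taxon), or `"as-given"` (returned unchanged).
#' @param outgroup Outgroup leaf label, required for the outgroup policy.
#' @return A rooted `phylo`; leaf set and non-root bipartitions (with their
#'   supports) are unchanged.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1)90:0.5,C:2);")
#' root_tree(tr, "outgroup", outgroup = "C")
root_tree <- function(tree, policy = c("midpoint", "outgroup", "as-given"),
                      outgroup = NULL) {
  policy <- match.arg(policy)
  if (policy == "as-given") return(tree)
  if (policy == "outgroup") {
    if (is.null(outgroup) || !(outgroup %in% tree$tip.label))
      abort_lgtree(sprintf("outgroup taxon '%s' is not a leaf of the tree",
                           outgroup %||% "<missing>"),
                   "lgtree_arg_error")
    tip <- match(outgroup, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == tip, 1]
    return(.reroot_at_edge(tree, tip, parent))
  }
  midpoint_root(tree)
}

#' Midpoint rooting
#'
#' Places the root halfway along the path realizing the tree diameter, which
#' minimizes the maximum root-to-leaf distance. Ties in the diameter pair are
#' broken by the lexicographically smallest leaf-label pair.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length))
    abort_lgtree("midpoint rooting needs branch lengths", "lgtree_arg_error")
  n <- length(tree$tip.label)
  if (n == 1) return(tree)
  dn <- ape::dist.nodes(tree)
  dl <- dn[seq_len(n), seq_len(n), drop = FALSE]
  dmax <- max(dl)
  cand <- which(dl >= dmax - 1e-12 * max(1, dmax), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  keys <- apply(cand, 1, function(ij) {
    p <- sort(tree$tip.label[ij])
    paste(p, collapse = "\r")
  })
  pick <- cand[order(keys)[1], ]
  u <- pick[1]; v <- pick[2]

  adj <- .tree_adjacency(tree)
  # path u -> v by DFS
  path <- .find_path(adj$nb, u, v)
  target <- dl[u, v] / 2
  cum <- 0
  for (k in seq_len(length(path) - 1)) {
    step <- adj$elen(path[k], path[k + 1])
    if (cum + step >= target - 1e-12) {
      return(.reroot_at_edge(tree, path[k], path[k + 1], target - cum))
    }
    cum <- cum + step
  }
  abort_lgtree("midpoint location not found on diameter path",
               "lgtree_internal_error")
}

.find_path <- function(nb, from, to) {
  prev <- integer(length(nb))
  seen <- logical(length(nb))
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (x == to) break
    for (y in nb[[x]]) if (!seen[y]) {
      seen[y] <- TRUE
      prev[y] <- x
      queue <- c(queue, y)
    }
  }
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}
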