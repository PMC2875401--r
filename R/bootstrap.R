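canonical_split <- function(side, all_labels) {
  anchor <- min(all_labels)
  if (anchor %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Builds the reference NJ tree from K2P distances on the full alignment,
#' then resamples alignment columns with replacement `replicates` times,
#' rebuilds the tree from each pseudo-alignment, and labels each internal
#' node of the reference tree with the percentage of replicate trees that
#' contain the same bipartition. A replicate in which a pairwise distance is
#' undefined (saturation) contributes no bipartitions but still counts in
#' the denominator.
#'
#' @param aln Character matrix (rows = taxa) or named character vector of
#'   aligned sequences; >= 4 sequences, >= 1 column.
#' @param replicates Number of bootstrap replicates (default 100).
#' @param seed Optional integer; same seed gives identical supports.
#' @param deletion Gap handling, see [k2p_matrix()].
#' @return The reference `phylo` tree with supports in \[0, 100\] as node
#'   labels (absent on the basal node).
#' @export
bootstrap_support <- function(aln, replicates = 100, seed = NULL,
                              deletion = "pairwise") {
  m <- as_char_alignment(aln)
  if (nrow(m) < 4)
    abort_lgtree("bootstrap needs >= 4 sequences", "lgtree_arg_error")
  if (ncol(m) == 0)
    abort_lgtree("alignment has zero columns", "lgtree_arg_error")
  if (replicates < 1)
    abort_lgtree("replicates must be >= 1", "lgtree_arg_error")

  ref <- neighbor_joining(k2p_matrix(m, deletion = deletion))
  labs <- ref$tip.label

  run <- function() {
    counts <- new.env(parent = emptyenv())
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      splits <- tryCatch(
        tree_bipartitions(
          neighbor_joining(k2p_matrix(m[, cols, drop = FALSE],
                                      deletion = deletion))),
        lgtree_error = function(e) character(0))
      for (s in splits)
        assign(s, (get0(s, envir = counts) %||% 0L) + 1L, envir = counts)
    }
    counts
  }
  counts <- if (is.null(seed)) run() else with_seed(seed, run())

  n <- length(labs)
  parts <- ape::prop.part(ref)
  supports <- rep(NA_real_, ref$Nnode)
  for (k in seq_len(ref$Nnode)) {
    side <- labs[parts[[k]]]
    if (length(side) < 2 || length(side) > n - 2) next  # basal/trivial
    key <- canonical_split(side, labs)
    supports[k] <- 100 * (get0(key, envir = counts) %||% 0L) / replicates
  }
  supports[1] <- NA_real_  # basal node of the unrooted tree: no split of its own
  set_node_supports(ref, supports)
}
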