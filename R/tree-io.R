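#' Read a Newick gene tree
#'
#' Parses a Newick string (or file) into an [ape::phylo] object. Numeric
#' internal-node labels are interpreted as bootstrap support values in
#' \[0, 100\]; unlabeled internal nodes carry absent support. Input is
#' validated before parsing: unbalanced parentheses raise an error naming the
#' offending character offset, and duplicate leaf labels are rejected.
#'
#' @param text Newick string. Exactly one of `text` or `file` must be given.
#' @param file Path to a Newick file.
#' @param support_dialect `"labels"` (default: supports are internal-node
#'   labels, the dominant dialect) or `"comments"` (supports in square-bracket
#'   comments after the closing parenthesis, e.g. `")[95]"`).
#' @return A `phylo` object; `node.label` holds the support strings.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1)95:0.5,C:2);")
#' node_supports(tr)
read_newick <- function(text = NULL, file = NULL,
                        support_dialect = c("labels", "comments")) {
  support_dialect <- match.arg(support_dialect)
  if (is.null(text) == is.null(file))
    abort_lgtree("give exactly one of `text` or `file`", "lgtree_arg_error")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1L)

  .check_parens(text)
  if (support_dialect == "comments") {
    text <- gsub("\\)\\s*\\[([0-9.eE+-]+)\\]", ")\\1", text)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree))
    abort_lgtree("Newick parse failed", "lgtree_parse_error")
  validate_gene_tree(tree)
  tree
}

.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack))
        abort_lgtree(
          sprintf("unbalanced ')' at character offset %d", i),
          "lgtree_parse_error", offset = i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    abort_lgtree(
      sprintf("unclosed '(' opened at character offset %d", stack[length(stack)]),
      "lgtree_parse_error", offset = stack[length(stack)])
  invisible(TRUE)
}

#' Validate a gene tree
#'
#' Checks the invariants expected of trees flowing through the pipeline:
#' unique leaf labels and, when support labels are present, values in
#' \[0, 100\].
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_gene_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    abort_lgtree(
      paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")),
      "lgtree_validation_error")
  s <- node_supports(tree)
  bad <- !is.na(s) & (s < 0 | s > 100)
  if (any(bad))
    abort_lgtree("support values outside [0, 100]", "lgtree_validation_error")
  invisible(tree)
}

#' Write a tree as Newick
#'
#' Supports (node labels) and branch lengths round-trip through
#' [read_newick()]; lengths are written with 10 significant digits.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Numeric support values per internal node
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (indexed in node order,
#'   i.e. element `i` is node `Ntip + i`); `NA` where support is absent or
#'   the label is non-numeric.
#' @export
node_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  lab[!nzchar(lab)] <- NA
  suppressWarnings(as.numeric(lab))
}

#' Set support values on internal nodes
#'
#' @param tree A `phylo` object.
#' @param value Numeric vector of length `tree$Nnode`; `NA` means absent.
#' @return The modified tree.
#' @export
set_node_supports <- function(tree, value) {
  stopifnot(length(value) == tree$Nnode)
  lab <- ifelse(is.na(value), "", format(value, trim = TRUE, digits = 10))
  tree$node.label <- lab
  tree
}

#' Canonical bipartition set of a tree
#'
#' Returns the non-trivial splits of the unrooted topology as canonical
#' strings (each split is represented by the side *not* containing the
#' lexicographically smallest leaf, sorted and joined with `|`). Two trees
#' have the same unrooted topology iff their bipartition sets are equal.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical splits (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  utree <- ape::unroot(tree)
  n <- length(utree$tip.label)
  if (n < 4) return(character(0))
  parts <- ape::prop.part(utree)
  labs <- utree$tip.label
  anchor <- min(labs)
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

#' Leaf labels descending from an internal node
#' @param tree A `phylo` object.
#' @param node Node number (may be a leaf, giving that leaf).
#' @return Character vector of tip labels.
#' @export
node_leaves <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- node
  tips <- integer(0)
  while (length(kids)) {
    ch <- tree$edge[tree$edge[, 1] %in% kids, 2]
    tips <- c(tips, ch[ch <= n])
    kids <- ch[ch > n]
  }
  tree$tip.label[tips]
}
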