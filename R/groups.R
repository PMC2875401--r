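default_group_vocabulary <- function() {
  c("cluster_IV", "cluster_XIVa", "cluster_I", "cluster_III", "cluster_XI",
    "other")
}

#' Taxon-to-group map
#'
#' Maps each taxon (leaf label) to its source species and its clade group
#' (e.g. *Clostridium* cluster IV / XIVa / other). The focal group is the
#' putative recipient lineage of the query sequences.
#'
#' @param taxon Character vector of taxon identifiers (unique).
#' @param species Character vector of species names (recycled from `taxon`
#'   when omitted).
#' @param group Character vector of group labels.
#' @param groups Group vocabulary; defaults to the built-in cluster labels
#'   plus any labels present in `group`.
#' @param focal Focal (recipient) group label; must be in the vocabulary.
#' @return An object of class `taxon_group_map`.
#' @export
taxon_group_map <- function(taxon, species = taxon, group,
                            groups = NULL, focal = "cluster_IV") {
  stopifnot(length(taxon) == length(group), length(species) == length(taxon))
  dup <- unique(taxon[duplicated(taxon)])
  if (length(dup))
    abort_lgtree(
      paste0("duplicate taxon in group map: ", paste(dup, collapse = ", ")),
      "lgtree_validation_error")
  groups <- unique(c(groups %||% default_group_vocabulary(), focal))
  unknown <- setdiff(unique(group), groups)
  if (length(unknown))
    abort_lgtree(
      paste0("undeclared group label(s): ", paste(unknown, collapse = ", ")),
      "lgtree_validation_error")
  structure(
    list(entries = data.frame(taxon = as.character(taxon),
                              species = as.character(species),
                              group = as.character(group),
                              stringsAsFactors = FALSE),
         groups = groups, focal = focal),
    class = "taxon_group_map")
}

#' @export
print.taxon_group_map <- function(x, ...) {
  cat(sprintf("taxon_group_map: %d taxa, focal group %s\n",
              nrow(x$entries), x$focal))
  tab <- table(x$entries$group)
  for (g in names(tab)) cat(sprintf("  %-14s %d\n", g, tab[[g]]))
  invisible(x)
}

group_of <- function(map, taxa) {
  idx <- match(taxa, map$entries$taxon)
  if (anyNA(idx))
    abort_lgtree(
      paste0("taxa missing from group map: ",
             paste(taxa[is.na(idx)], collapse = ", ")),
      "lgtree_validation_error")
  map$entries$group[idx]
}

species_of <- function(map, taxa) {
  idx <- match(taxa, map$entries$taxon)
  if (anyNA(idx))
    abort_lgtree(
      paste0("taxa missing from group map: ",
             paste(taxa[is.na(idx)], collapse = ", ")),
      "lgtree_validation_error")
  map$entries$species[idx]
}

#' Read a taxon-group map from TSV
#'
#' Expects two or three tab-separated columns: taxon, \[species,\] group.
#' A comment header line starting `#groups:` may declare extra group labels
#' (comma separated); labels outside the vocabulary are otherwise rejected.
#' An empty file yields an empty, valid map.
#'
#' @param path Path to the TSV file.
#' @param focal Focal group label.
#' @return A [taxon_group_map()].
#' @export
read_group_map <- function(path, focal = "cluster_IV") {
  lines <- readLines(path, warn = FALSE)
  declared <- NULL
  hdr <- grep("^#groups:", lines, value = TRUE)
  if (length(hdr))
    declared <- trimws(strsplit(sub("^#groups:", "", hdr[1]), ",")[[1]])
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(taxon_group_map(character(0), character(0), character(0),
                           groups = declared, focal = focal))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2))
    abort_lgtree("group map rows need >= 2 tab-separated fields",
                 "lgtree_parse_error")
  taxon <- vapply(parts, `[[`, "", 1L)
  group <- vapply(parts, function(p) p[[length(p)]], "")
  species <- vapply(parts, function(p) if (length(p) >= 3) p[[2L]] else p[[1L]], "")
  taxon_group_map(taxon, species, group, groups = declared, focal = focal)
}

#' Write a taxon-group map as TSV
#' @param map A [taxon_group_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(map, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#groups: %s", paste(map$groups, collapse = ",")), con)
  writeLines("#taxon\tspecies\tgroup", con)
  with(map$entries,
       writeLines(paste(taxon, species, group, sep = "\t"), con))
  invisible(path)
}

#' Classifier configuration
#'
#' Bundles the thresholds of the LGT tree-walk classifier: genes whose best
#' reference hit has e-value above `evalue_threshold` are "novel" (too
#' divergent to place); the walk from the query toward the root stops at the
#' first node with bootstrap support strictly greater than
#' `support_threshold` that contains a sequence from a different species.
#'
#' @param evalue_threshold Positive e-value cut-off for the novelty gate
#'   (default `1e-6`, strict `>` comparison).
#' @param support_threshold Support gate in \[0, 100\] (default 60, strict
#'   `>` comparison).
#' @param focal_group Recipient group label (default `"cluster_IV"`).
#' @param rooting Rooting policy applied to unrooted input trees:
#'   `"midpoint"`, `"as-given"`, or `"outgroup"`.
#' @param outgroup Outgroup taxon, required when `rooting = "outgroup"`.
#' @param low_support_flag Calls whose decision-node support is below this
#'   value are flagged `low_support` in reports (report-only tier; default
#'   70).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(evalue_threshold = 1e-6,
                              support_threshold = 60,
                              focal_group = "cluster_IV",
                              rooting = c("midpoint", "as-given", "outgroup"),
                              outgroup = NULL,
                              low_support_flag = 70) {
  rooting <- match.arg(rooting)
  if (!is.numeric(evalue_threshold) || evalue_threshold <= 0)
    abort_lgtree("evalue_threshold must be > 0", "lgtree_arg_error")
  if (support_threshold < 0 || support_threshold > 100)
    abort_lgtree("support_threshold must be in [0, 100]", "lgtree_arg_error")
  if (rooting == "outgroup" && is.null(outgroup))
    abort_lgtree("outgroup rooting needs an `outgroup` taxon",
                 "lgtree_arg_error")
  structure(
    list(evalue_threshold = evalue_threshold,
         support_threshold = support_threshold,
         focal_group = focal_group,
         rooting = rooting,
         outgroup = outgroup,
         low_support_flag = low_support_flag),
    class = "classifier_config")
}
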