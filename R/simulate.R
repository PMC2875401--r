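#' Simulation scenario
#'
#' Describes one synthetic gene-tree world: the group vocabulary with clade
#' sizes, the planted event, the bootstrap-support regime on the nodes the
#' classifier will walk through, and the sequence-evolution parameters used
#' by [evolve_alignment()]. Identical scenario + seed gives byte-identical
#' outputs.
#'
#' @param event `"none"` (query sits in its own focal clade) or
#'   `"transfer"` (query grafted inside a pure donor clade).
#' @param donor Donor group for `event = "transfer"`; must be a non-focal
#'   member of the vocabulary.
#' @param focal Focal (recipient) group label.
#' @param clade_sizes Named integer vector: leaves per group clade (all
#'   >= 1). Defaults emulate the modest per-gene reference sets of
#'   single-copy bacterial gene trees.
#' @param support_regime `"pass"` (supports on the walked nodes drawn
#'   uniformly from 80-100, above the >60 gate) or `"fail"` (uniform 0-60,
#'   never above it).
#' @param seq_length Alignment length for sequence evolution.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(event = c("none", "transfer"),
                         donor = "cluster_XIVa", focal = "cluster_IV",
                         clade_sizes = c(cluster_IV = 6, cluster_XIVa = 5,
                                         other = 4),
                         support_regime = c("pass", "fail"),
                         seq_length = 1000, kappa = 2, seed = 1) {
  event <- match.arg(event)
  support_regime <- match.arg(support_regime)
  if (any(clade_sizes < 1))
    abort_lgtree("clade sizes must be >= 1", "lgtree_arg_error")
  if (event == "transfer" && !(donor %in% names(clade_sizes)))
    abort_lgtree(sprintf("donor group '%s' absent from vocabulary", donor),
                 "lgtree_arg_error")
  if (event == "transfer" && donor == focal)
    abort_lgtree("donor must differ from the focal group", "lgtree_arg_error")
  if (seq_length < 1 || kappa <= 0)
    abort_lgtree("seq_length must be >= 1 and kappa > 0", "lgtree_arg_error")
  structure(list(event = event, donor = donor, focal = focal,
                 clade_sizes = clade_sizes,
                 support_regime = support_regime,
                 seq_length = seq_length, kappa = kappa,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

.draw_support <- function(n, regime) {
  switch(regime,
         pass = runif(n, 80, 100),
         fail = runif(n, 0, 60))
}

# caterpillar Newick for a clade of labelled leaves with given node supports
.clade_newick <- function(leaves, supports, bl) {
  s <- sprintf("%s:%.6f", leaves[1], bl())
  if (length(leaves) == 1) return(s)
  for (k in 2:length(leaves)) {
    s <- sprintf("(%s,%s:%.6f)%.4f:%.6f", s, leaves[k], bl(),
                 supports[k - 1], bl())
  }
  s
}

#' Simulate a gene tree with a planted transfer event
#'
#' Builds a rooted, fully labelled gene tree in which the truth is known by
#' construction: under `event = "transfer"` the query leaf is grafted as the
#' innermost taxon of a pure donor-group clade whose subtending nodes draw
#' supports from the scenario's regime, so a gate-passing regime makes the
#' query's first supported ancestor a pure-donor decision node (truth:
#' `lgt`, direction from donor to focal); under `event = "none"` the query
#' sits inside its focal clade (truth: `no_lgt`). With the `"fail"` regime
#' no node on the query's root path passes the gate (truth: `unresolved`).
#' Supports are drawn directly from truncated uniform regimes rather than
#' bootstrap-computed, keeping classifier tests independent of tree
#' construction. Every leaf is its own species.
#'
#' @param sc A [sim_scenario()].
#' @return List with `tree` (rooted `phylo` with supports), `truth` (an
#'   [lgt_call()]), `groups` (a [taxon_group_map()]), and `query` (leaf
#'   label, always `"QUERY"`).
#' @export
simulate_gene_tree <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  with_seed(sc$seed, {
    bl <- function() runif(1, 0.02, 0.2)
    groups <- names(sc$clade_sizes)
    leaves <- lapply(groups, function(g)
      sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", g), seq_len(sc$clade_sizes[[g]])))
    names(leaves) <- groups

    host <- if (sc$event == "transfer") sc$donor else sc$focal
    host_leaves <- c("QUERY", leaves[[host]])
    # nodes subtending the query draw from the scenario regime
    host_sup <- .draw_support(length(host_leaves) - 1, sc$support_regime)
    host_clade <- .clade_newick(host_leaves, host_sup, bl)

    other_clades <- vapply(setdiff(groups, host), function(g) {
      n <- length(leaves[[g]])
      .clade_newick(leaves[[g]], .draw_support(max(n - 1, 0), "pass"), bl)
    }, "")

    # spine nodes above the host clade sit on the query's root path: they
    # must not pass the gate in the "fail" regime
    spine <- host_clade
    for (cl in other_clades) {
      spine <- sprintf("(%s,%s)%.4f:%.6f", spine, cl,
                       .draw_support(1, sc$support_regime), bl())
    }
    tree <- ape::read.tree(text = paste0(sub(":[0-9.]+$", "", spine), ";"))
    tree$node.label[1] <- ""  # the root carries no support

    entries_taxon <- c("QUERY", unlist(leaves, use.names = FALSE))
    entries_group <- c(sc$focal,
                       rep(groups, times = lengths(leaves)))
    map <- taxon_group_map(entries_taxon,
                           species = paste0("sp_", entries_taxon),
                           group = entries_group,
                           groups = unique(c(groups, sc$focal)),
                           focal = sc$focal)

    truth <- if (sc$event == "transfer" && sc$support_regime == "pass") {
      lgt_call("QUERY", "lgt", query = "QUERY", donor = sc$donor,
               decision_groups = sc$donor,
               direction = sprintf("from_%s_to_%s", sc$donor, sc$focal),
               method = "truth")
    } else if (sc$event == "none" && sc$support_regime == "pass") {
      lgt_call("QUERY", "no_lgt", query = "QUERY", method = "truth")
    } else {
      lgt_call("QUERY", "unresolved", query = "QUERY", method = "truth")
    }

    list(tree = tree, truth = truth, groups = map, query = "QUERY")
  })
}

#' Evolve an alignment along a tree under the two-parameter process
#'
#' Sites evolve independently down the tree from a uniform-random root
#' sequence. On a branch of length `d` substitutions/site with
#' transition/transversion rate ratio `kappa`, the per-site substitution
#' probabilities follow the Kimura model: transitions occur with probability
#' `1/4 + exp(-4*beta*t)/4 - exp(-2*(alpha+beta)*t)/2` and each transversion
#' with half of `1/2 - exp(-4*beta*t)/2`, where `alpha*t` and `beta*t` are
#' recovered from `d = (alpha + 2*beta)*t`.
#'
#' @param tree `phylo` with branch lengths (error if any is missing).
#' @param n_sites Alignment length (columns).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed; same inputs give identical alignments.
#' @return Character matrix (rows = taxa) of A/C/G/T.
#' @export
evolve_alignment <- function(tree, n_sites = 1000, kappa = 2, seed = 1) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    abort_lgtree("evolve_alignment needs branch lengths on every edge",
                 "lgtree_arg_error")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
  transversion_partners <- list(A = c("C", "T"), G = c("C", "T"),
                                C = c("A", "G"), T = c("A", "G"))

  mutate <- function(seq, d) {
    if (d <= 0) return(seq)
    bt <- d / (kappa + 2)
    at <- kappa * bt
    p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
    p_tv <- 0.5 - 0.5 * exp(-4 * bt)  # total over both transversions
    u <- runif(length(seq))
    out <- seq
    ts <- u < p_ts
    tv1 <- !ts & u < p_ts + p_tv / 2
    tv2 <- !ts & !tv1 & u < p_ts + p_tv
    out[ts] <- transition_partner[seq[ts]]
    out[tv1] <- vapply(seq[tv1], function(b) transversion_partners[[b]][1], "")
    out[tv2] <- vapply(seq[tv2], function(b) transversion_partners[[b]][2], "")
    out
  }

  with_seed(seed, {
    seqs <- vector("list", nn)
    root <- n + 1L
    seqs[[root]] <- sample(.BASES, n_sites, replace = TRUE)
    # preorder: parent sequences exist before children are visited
    ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2]])
    for (k in ord) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      seqs[[ch]] <- mutate(seqs[[p]], tree$edge.length[k])
    }
    m <- do.call(rbind, seqs[seq_len(n)])
    rownames(m) <- tree$tip.label
    m
  })
}

#' Simulate a BLAST tabular hit set with controlled per-genus e-values
#'
#' Each genus receives exactly its requested number of hits, with
#' `-log10(e-value)` drawn uniformly from the genus's magnitude range.
#'
#' @param genus_counts Named integer vector: hits per genus.
#' @param magnitude_ranges Named list of `c(lo, hi)` exponent ranges per
#'   genus (default 3-150 for all).
#' @param seed Integer seed.
#' @return data.frame with columns `query`, `subject`, `pident`, `evalue`,
#'   `bitscore`, `species`, `genus`.
#' @export
simulate_blast_hits <- function(genus_counts,
                                magnitude_ranges = NULL, seed = 1) {
  stopifnot(length(genus_counts) > 0, !is.null(names(genus_counts)))
  with_seed(seed, {
    rows <- lapply(names(genus_counts), function(g) {
      k <- genus_counts[[g]]
      rng <- magnitude_ranges[[g]] %||% c(3, 150)
      mag <- runif(k, rng[1], rng[2])
      data.frame(query = sprintf("orf_%s_%d", g, seq_len(k)),
                 subject = sprintf("%s_subj_%d", g, seq_len(k)),
                 pident = round(runif(k, 30, 100), 1),
                 evalue = 10^(-mag),
                 bitscore = round(runif(k, 50, 500), 1),
                 species = sprintf("%s sp%d", g, seq_len(k)),
                 genus = g, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write simulated hits as a BLAST outfmt-6-compatible TSV
#'
#' Twelve standard columns (placeholders for the alignment coordinates) plus
#' species and genus.
#'
#' @param hits data.frame from [simulate_blast_hits()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#qseqid\tsseqid\tpident\tlength\tmismatch\tgapopen\tqstart\tqend\tsstart\tsend\tevalue\tbitscore\tspecies\tgenus", con)
  writeLines(sprintf("%s\t%s\t%.1f\t100\t0\t0\t1\t100\t1\t100\t%.6e\t%.1f\t%s\t%s",
                     hits$query, hits$subject, hits$pident,
                     hits$evalue, hits$bitscore, hits$species, hits$genus),
             con)
  invisible(path)
}
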