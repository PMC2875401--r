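#' Recount the headline statistics from the fosmid gene-table fixture
#'
#' A pure function of the fixture: recomputes, from the per-method LGT
#' assessments and the top-hit annotations alone, the counts a reader would
#' tally from the printed gene table. The "LGT count" uses the conservative
#' reconciliation of the NJ and ML assessments (see [reconcile_methods()]).
#' Percentages are rounded half-up to whole percent; raw fractions are also
#' returned.
#'
#' @param fixture data.frame from [load_table1_fixture()].
#' @return A list of counts: `coding_total`, `lgt_count`,
#'   `donor_xiva_count`, `nonfocal_tophit_count`, `nonfocal_tophit_pct`
#'   (rounded) and `nonfocal_tophit_frac`, `transposase_count`,
#'   `native_transposase_count`, `integrase_count`, `discordance_count`,
#'   plus per-status totals of the reconciled calls.
#' @export
#' @examples
#' recount_fixture(load_table1_fixture())
recount_fixture <- function(fixture) {
  cds <- fixture[fixture$feature_class == "protein_coding", , drop = FALSE]
  reconciled <- mapply(reconcile_status, cds$lgt_nj, cds$lgt_ml)
  is_lgt <- reconciled == "lgt"
  donor_xiva <- is_lgt & cds$direction == "from_cluster_XIVa_to_cluster_IV"
  nonfocal <- !cds$top_focal
  transposase <- grepl("transposase", cds$func, ignore.case = TRUE)
  integrase <- grepl("integrase", cds$func, ignore.case = TRUE)

  list(
    coding_total = nrow(cds),
    lgt_count = sum(is_lgt),
    donor_xiva_count = sum(donor_xiva),
    nonfocal_tophit_count = sum(nonfocal),
    nonfocal_tophit_frac = sum(nonfocal) / nrow(cds),
    nonfocal_tophit_pct = round_half_up(100 * sum(nonfocal) / nrow(cds)),
    transposase_count = sum(transposase),
    native_transposase_count = sum(transposase & reconciled == "no_lgt"),
    integrase_count = sum(integrase),
    discordance_count = sum(cds$lgt_nj != cds$lgt_ml),
    no_lgt_count = sum(reconciled == "no_lgt"),
    novel_count = sum(reconciled == "novel"),
    unresolved_count = sum(reconciled == "unresolved"))
}

#' Run configuration for an end-to-end analysis
#'
#' @param manifest Path to a TSV with columns: gene id, query leaf label,
#'   NJ tree file, optional ML tree file, top-hit e-value.
#' @param groups Path to a taxon-group map TSV (see [read_group_map()]).
#' @param out_dir Output directory (created if missing).
#' @param classifier A [classifier_config()].
#' @param hits Optional BLAST hits TSV for a profile matrix.
#' @param min_hits Profile row threshold.
#' @param seed Seed recorded in output headers (the classifier itself is
#'   deterministic).
#' @param policy Reconciliation policy.
#' @return An object of class `run_config`; referenced paths are checked at
#'   validation time.
#' @export
run_config <- function(manifest, groups, out_dir,
                       classifier = classifier_config(),
                       hits = NULL, min_hits = 10, seed = 1,
                       policy = "conservative") {
  for (p in c(manifest, groups, hits)) {
    if (!file.exists(p))
      abort_lgtree(sprintf("path does not exist: %s", p), "lgtree_arg_error")
  }
  structure(list(manifest = manifest, groups = groups, out_dir = out_dir,
                 classifier = classifier, hits = hits, min_hits = min_hits,
                 seed = as.integer(seed), policy = policy),
            class = "run_config")
}

.read_manifest <- function(path) {
  df <- read.delim(path, comment.char = "#", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 4)
    abort_lgtree("manifest needs >= 4 columns: gene, query, nj_tree, [ml_tree,] evalue",
                 "lgtree_parse_error")
  names(df)[1:3] <- c("gene_id", "query", "nj_tree")
  if (ncol(df) >= 5) {
    names(df)[4:5] <- c("ml_tree", "evalue")
  } else {
    names(df)[4] <- "evalue"
    df$ml_tree <- NA_character_
  }
  df$evalue <- as.numeric(df$evalue)
  df
}

.call_header <- function(cfg) {
  c(sprintf("#lgtree %s", as.character(utils::packageVersion("lgtree"))),
    sprintf("#seed\t%d", cfg$seed),
    sprintf("#support_threshold\t%g", cfg$classifier$support_threshold),
    sprintf("#evalue_threshold\t%g", cfg$classifier$evalue_threshold),
    sprintf("#focal_group\t%s", cfg$classifier$focal_group),
    sprintf("#policy\t%s", cfg$policy))
}

.call_row <- function(x) {
  paste(x$gene_id, x$method, x$status,
        ifelse(is.na(x$decision_support), ".",
               sprintf("%.4g", x$decision_support)),
        if (length(x$decision_groups)) paste(x$decision_groups, collapse = ",")
        else ".",
        x$donor %||% ".", x$direction,
        if (isTRUE(x$low_support)) "low_support" else ".",
        sep = "\t")
}

#' Run the end-to-end LGT analysis
#'
#' For each manifest gene: read the NJ (and optional ML) Newick tree, root
#' it per the configured policy when unrooted, classify it with the
#' bootstrap-gated tree walk, infer the transfer direction for LGT calls by
#' Fitch parsimony, and reconcile the two methods. Writes `calls.tsv` (one
#' row per gene and method, including the reconciled call), `summary.tsv`,
#' and, when hits are configured, `profile.tsv`. Every gate decision is
#' logged to stderr for auditability. Outputs are deterministic for a fixed
#' config and seed.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-gene log messages.
#' @return Invisibly, a list with `calls` (list of reconciled
#'   [lgt_call()]s), `summary`, and optionally `profile`.
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- .read_manifest(cfg$manifest)
  groups <- read_group_map(cfg$groups, focal = cfg$classifier$focal_group)
  ccfg <- cfg$classifier
  log <- function(...) if (!quiet) message(sprintf(...))

  calls <- vector("list", nrow(manifest))
  rows <- character(0)
  for (i in seq_len(nrow(manifest))) {
    g <- manifest[i, ]
    stage <- "nj"
    res <- tryCatch({
      njt <- read_newick(file = g$nj_tree)
      nj_call <- classify_and_infer(njt, g$query, groups, g$evalue, ccfg,
                                    gene_id = g$gene_id, method = "nj")
      log("[%s] nj: %s (support %s)", g$gene_id, nj_call$status,
          format(nj_call$decision_support))
      if (!is.na(g$ml_tree) && nzchar(g$ml_tree)) {
        stage <- "ml"
        mlt <- read_newick(file = g$ml_tree)
        ml_call <- classify_and_infer(mlt, g$query, groups, g$evalue, ccfg,
                                      gene_id = g$gene_id, method = "ml")
        log("[%s] ml: %s", g$gene_id, ml_call$status)
        stage <- "reconcile"
        rec <- reconcile_methods(nj_call, ml_call, policy = cfg$policy)
        rows <- c(rows, .call_row(nj_call), .call_row(ml_call), .call_row(rec))
        rec
      } else {
        rows <- c(rows, .call_row(nj_call))
        nj_call
      }
    }, lgtree_error = function(e) {
      abort_lgtree(sprintf("stage '%s' failed for gene '%s': %s",
                           stage, g$gene_id, conditionMessage(e)),
                   "lgtree_pipeline_error")
    })
    calls[[i]] <- res
  }

  hdr <- .call_header(cfg)
  calls_path <- file.path(cfg$out_dir, "calls.tsv")
  writeLines(c(hdr,
               "#gene\tmethod\tstatus\tdecision_support\tdecision_groups\tdonor\tdirection\tflags",
               rows), calls_path)

  smry <- summarize_calls(calls)
  summary_path <- file.path(cfg$out_dir, "summary.tsv")
  donor_str <- if (length(smry$per_donor))
    paste(sprintf("%s=%d", names(smry$per_donor), smry$per_donor),
          collapse = ",") else "."
  writeLines(c(hdr, "#metric\tvalue",
               sprintf("total\t%d", smry$total),
               sprintf("novel\t%d", smry$novel),
               sprintf("no_lgt\t%d", smry$no_lgt),
               sprintf("unresolved\t%d", smry$unresolved),
               sprintf("lgt\t%d", smry$lgt),
               sprintf("direction_resolved\t%d", smry$direction_resolved),
               sprintf("per_donor\t%s", donor_str),
               sprintf("discordant\t%d", smry$discordant)), summary_path)

  out <- list(calls = calls, summary = smry)
  if (!is.null(cfg$hits)) {
    pm <- build_profile(read_blast_hits(cfg$hits), min_hits = cfg$min_hits)
    render_profile(pm, file.path(cfg$out_dir, "profile.tsv"))
    out$profile <- pm
  }
  invisible(out)
}
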