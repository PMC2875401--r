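#' Default e-value bin edges for profile matrices
#'
#' One-decade bins from 1e0 down to 1e-180; hits below the last edge
#' (including e-value 0) fall in a final most-significant bin. 1e-80, the
#' conventional conserved-sequence landmark, is always an edge.
#'
#' @param from,to,by Exponents of 10 for the first edge, last edge, and step.
#' @return Strictly decreasing numeric vector of e-value edges.
#' @export
default_evalue_edges <- function(from = 0, to = -180, by = -10) {
  10^seq(from, to, by = by)
}

#' Read BLAST tabular hits with appended taxonomy columns
#'
#' Expects outfmt-6-compatible columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) plus two appended
#' columns: subject species and subject genus. Lines starting `#` are
#' ignored.
#'
#' @param path TSV path.
#' @return data.frame with columns `query`, `subject`, `pident`, `evalue`,
#'   `bitscore`, `species`, `genus`.
#' @export
read_blast_hits <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 14)
    abort_lgtree("expected >= 14 columns (outfmt 6 + species + genus)",
                 "lgtree_parse_error")
  data.frame(query = as.character(df[[1]]), subject = as.character(df[[2]]),
             pident = as.numeric(df[[3]]), evalue = as.numeric(df[[11]]),
             bitscore = as.numeric(df[[12]]),
             species = as.character(df[[13]]), genus = as.character(df[[14]]),
             stringsAsFactors = FALSE)
}

#' Build a genus (or group) x e-value-range hit-frequency matrix
#'
#' Every accepted hit is assigned to exactly one e-value bin (bins are
#' half-open, `(edge[i+1], edge[i]]`, with a final bin for hits at or below
#' the last edge, including e-value 0); rows whose total falls below
#' `min_hits` are dropped; hits with e-value above the first edge are
#' counted in an overflow tally and reported in the metadata. No per-ORF
#' deduplication is performed: all hits per genus per query are accepted.
#'
#' @param hits data.frame with columns `evalue` and `genus` (and `species`
#'   when `row_mode = "custom"`).
#' @param bins Strictly decreasing e-value edges (see
#'   [default_evalue_edges()]).
#' @param min_hits Minimum row total for a row to be retained.
#' @param row_mode `"genus"` or `"custom"` (rows are group labels resolved
#'   through `group_map`; unmappable species go to an `"unassigned"` row
#'   with a warning).
#' @param group_map A [taxon_group_map()] for `row_mode = "custom"`.
#' @param row_order Optional character vector fixing row order (e.g. a
#'   phylogenetic ordering); rows not listed are appended alphabetically.
#' @return An object of class `profile_matrix`: `counts` (matrix), `edges`,
#'   `min_hits`, `total_input`, `overflow`, `dropped_rows`, `dropped_total`.
#' @export
build_profile <- function(hits, bins = default_evalue_edges(), min_hits = 10,
                          row_mode = c("genus", "custom"), group_map = NULL,
                          row_order = NULL) {
  row_mode <- match.arg(row_mode)
  if (any(diff(bins) >= 0))
    abort_lgtree("bin edges must be strictly decreasing e-values",
                 "lgtree_arg_error")
  ev <- hits$evalue
  if (any(is.na(ev) | ev < 0))
    abort_lgtree("hit e-values must be >= 0", "lgtree_validation_error")

  rows <- if (row_mode == "genus") {
    if (any(!nzchar(hits$genus)))
      abort_lgtree("empty genus in hits", "lgtree_validation_error")
    hits$genus
  } else {
    if (is.null(group_map))
      abort_lgtree("custom row mode needs a group_map", "lgtree_arg_error")
    idx <- match(hits$species, group_map$entries$species)
    g <- group_map$entries$group[idx]
    if (anyNA(idx)) {
      warning(sprintf("%d hit(s) with unmappable species assigned to 'unassigned'",
                      sum(is.na(idx))), call. = FALSE)
      g[is.na(idx)] <- "unassigned"
    }
    g
  }

  nb <- length(bins)  # nb-1 interior bins + 1 most-significant bin
  col_labels <- c(sprintf("(%.3g,%.3g]", bins[-1], bins[-nb]),
                  sprintf("<=%.3g", bins[nb]))
  overflow <- ev > bins[1]
  # bin index: first interior bin i with ev > bins[i+1]; else the final bin
  bin_idx <- rep(nb, length(ev))
  for (i in seq_len(nb - 1)) {
    sel <- bin_idx == nb & ev > bins[i + 1] & ev <= bins[i]
    bin_idx[sel] <- i
  }
  keep <- !overflow
  lev <- sort(unique(rows))
  if (length(lev)) {
    tab <- table(factor(rows[keep], levels = lev),
                 factor(bin_idx[keep], levels = seq_len(nb)))
    counts <- matrix(as.integer(tab), nrow = nrow(tab),
                     dimnames = list(rownames(tab), col_labels))
  } else {
    counts <- matrix(integer(0), nrow = 0, ncol = nb,
                     dimnames = list(NULL, col_labels))
  }

  totals <- rowSums(counts)
  retained <- totals >= min_hits
  dropped_total <- as.integer(sum(totals[!retained]))
  dropped_rows <- rownames(counts)[!retained]
  counts <- counts[retained, , drop = FALSE]

  if (!is.null(row_order)) {
    ord <- c(intersect(row_order, rownames(counts)),
             sort(setdiff(rownames(counts), row_order)))
    counts <- counts[ord, , drop = FALSE]
  }

  structure(list(counts = counts, edges = bins, min_hits = min_hits,
                 total_input = length(ev), overflow = as.integer(sum(overflow)),
                 dropped_rows = dropped_rows, dropped_total = dropped_total),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "profile_matrix: %d row(s) x %d bin(s); %d/%d hits in matrix (%d dropped with %d row(s), %d overflow)\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts), x$total_input,
    x$dropped_total, length(x$dropped_rows), x$overflow))
  nz <- colSums(x$counts) > 0
  if (any(nz)) print(x$counts[, nz, drop = FALSE])
  invisible(x)
}

#' Write a profile matrix as TSV (heat-map table)
#'
#' Emits the counts and, optionally, log10(count + 1)-scaled values in a
#' deterministic row/column order, with `#`-prefixed header lines carrying
#' the metadata needed to re-read the matrix.
#'
#' @param pm A [build_profile()] result.
#' @param file Output TSV path.
#' @param scale `"log10"` (log10(count + 1)) or `"linear"`.
#' @return `file`, invisibly.
#' @export
render_profile <- function(pm, file, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("#edges\t%s", paste(sprintf("%.17g", pm$edges), collapse = ",")),
    sprintf("#min_hits\t%d", pm$min_hits),
    sprintf("#total_input\t%d", pm$total_input),
    sprintf("#overflow\t%d", pm$overflow),
    sprintf("#dropped_rows\t%s", paste(pm$dropped_rows, collapse = ",")),
    sprintf("#dropped_total\t%d", pm$dropped_total),
    sprintf("#scale\t%s", scale),
    paste(c("row", colnames(pm$counts)), collapse = "\t")), con)
  vals <- if (scale == "log10") log10(pm$counts + 1) else pm$counts
  for (i in seq_len(nrow(pm$counts))) {
    writeLines(paste(c(rownames(pm$counts)[i],
                       format(vals[i, ], trim = TRUE, digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' Re-read a profile matrix written by [render_profile()]
#'
#' Counts are recovered exactly (the log10 scale is inverted).
#'
#' @param file TSV path.
#' @return A `profile_matrix`.
#' @export
read_profile <- function(file) {
  lines <- readLines(file, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  getm <- function(keyname) {
    ln <- meta[startsWith(meta, paste0("#", keyname, "\t"))]
    if (!length(ln)) return("")
    sub(paste0("^#", keyname, "\t"), "", ln[1])
  }
  edges <- as.numeric(strsplit(getm("edges"), ",")[[1]])
  scale <- getm("scale")
  body <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- body[-1]
  counts <- matrix(0L, nrow = length(rows), ncol = length(hdr) - 1,
                   dimnames = list(NULL, hdr[-1]))
  rn <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    rn[i] <- f[1]
    v <- as.numeric(f[-1])
    if (scale == "log10") v <- 10^v - 1
    counts[i, ] <- as.integer(round(v))
  }
  rownames(counts) <- rn
  dropped <- strsplit(getm("dropped_rows"), ",")[[1]]
  structure(list(counts = counts, edges = edges,
                 min_hits = as.integer(getm("min_hits")),
                 total_input = as.integer(getm("total_input")),
                 overflow = as.integer(getm("overflow")),
                 dropped_rows = if (length(dropped)) dropped else character(0),
                 dropped_total = as.integer(getm("dropped_total"))),
            class = "profile_matrix")
}
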