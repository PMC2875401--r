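#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`. Ambiguity codes and gaps are excluded
#' from both numerator and denominator.
#'
#' @param seq Nucleotide sequence (string, character vector, or
#'   `Biostrings::DNAString`).
#' @return GC percent in \[0, 100\].
#' @export
#' @examples
#' gc_content("GGCC")  # 100
gc_content <- function(seq) {
  s <- .as_base_vector(seq)
  s <- s[s %in% .BASES]
  if (!length(s))
    abort_lgtree("GC content undefined: no unambiguous A/C/G/T bases",
                 "lgtree_undefined_error")
  100 * sum(s %in% c("G", "C")) / length(s)
}

.as_base_vector <- function(seq) {
  if (inherits(seq, "XString")) seq <- as.character(seq)
  if (is.character(seq) && length(seq) == 1) seq <- strsplit(seq, "")[[1]]
  toupper(seq)
}

#' Reverse complement
#' @param seq Nucleotide string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' The 61 sense codons in alphabetical order
#' @return Character vector of codons (stops excluded).
#' @export
sense_codons <- function() {
  all64 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  all64 <- sort(all64)
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Codon-usage vector of a CDS set
#'
#' Aggregates codon counts across a set of in-frame coding sequences and
#' normalizes them either to overall relative frequencies across the 61
#' sense codons (default) or per amino acid (RSCU-like). A terminal stop
#' codon is allowed and excluded; internal stops trigger a warning and the
#' offending CDS is skipped (or an error with `on_internal_stop = "fail"`).
#'
#' @param cds_set Character vector of nucleotide CDS (each length divisible
#'   by 3, already on the coding strand — reverse-strand genes must be
#'   reverse-complemented first, e.g. with [reverse_complement()]).
#' @param mode `"overall"` or `"rscu"`.
#' @param on_internal_stop `"skip"` (warn and drop the CDS) or `"fail"`.
#' @return An object of class `codon_usage`: `counts` (61 named sense-codon
#'   counts), `freq` (normalized vector), `mode`, `n_cds`, `n_codons`.
#' @export
codon_usage <- function(cds_set, mode = c("overall", "rscu"),
                        on_internal_stop = c("skip", "fail")) {
  mode <- match.arg(mode)
  on_internal_stop <- match.arg(on_internal_stop)
  stops <- c("TAA", "TAG", "TGA")
  codons <- sense_codons()
  counts <- setNames(integer(length(codons)), codons)
  n_cds <- 0L
  nm <- names(cds_set) %||% paste0("CDS", seq_along(cds_set))
  for (i in seq_along(cds_set)) {
    s <- toupper(cds_set[[i]])
    if (nchar(s) %% 3 != 0)
      abort_lgtree(sprintf("CDS '%s' length %d is not divisible by 3",
                           nm[i], nchar(s)),
                   "lgtree_validation_error")
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    internal <- cod[-length(cod)] %in% stops
    if (any(internal)) {
      msg <- sprintf("CDS '%s' contains %d internal stop codon(s)",
                     nm[i], sum(internal))
      if (on_internal_stop == "fail")
        abort_lgtree(msg, "lgtree_validation_error")
      warning(msg, call. = FALSE)
      next
    }
    if (cod[length(cod)] %in% stops) cod <- cod[-length(cod)]
    tab <- table(factor(cod, levels = codons))
    counts <- counts + as.integer(tab)
    n_cds <- n_cds + 1L
  }
  total <- sum(counts)
  freq <- if (mode == "overall") {
    if (total > 0) counts / total else counts * 0
  } else {
    .rscu(counts)
  }
  structure(list(counts = counts, freq = freq, mode = mode,
                 n_cds = n_cds, n_codons = total),
            class = "codon_usage")
}

.rscu <- function(counts) {
  aa <- vapply(names(counts), function(c3) {
    as.character(Biostrings::translate(Biostrings::DNAString(c3)))
  }, "")
  out <- counts * 0
  for (a in unique(aa)) {
    idx <- aa == a
    tot <- sum(counts[idx])
    out[idx] <- if (tot > 0) counts[idx] * sum(idx) / tot else 0
  }
  out
}

#' Pearson correlation between two codon-usage vectors
#'
#' @param u,v [codon_usage()] objects with matching mode.
#' @return List with `r` (Pearson coefficient over the 61 sense-codon
#'   frequencies), `p` (two-sided p-value from the t transform with n-2
#'   degrees of freedom), `n`, and the normalization `mode`.
#' @export
usage_correlation <- function(u, v) {
  stopifnot(inherits(u, "codon_usage"), inherits(v, "codon_usage"))
  if (u$mode != v$mode)
    abort_lgtree("codon-usage vectors use different normalization modes",
                 "lgtree_arg_error")
  x <- as.numeric(u$freq); y <- as.numeric(v$freq)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_lgtree("correlation undefined: zero variance", "lgtree_undefined_error")
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n, mode = u$mode)
}

#' Percent identity between two sequences
#'
#' Identity is `100 * matches / columns`, where columns excludes gap-gap
#' pairs and, by default, terminal overhangs (end-gap-free convention, the
#' one that reproduces "percent similarity" figures quoted for near
#' full-length rRNA comparisons). `mode = "global-align"` aligns the
#' sequences first (match 1, mismatch -1, gap open -2, gap extend -0.5,
#' overlap-type alignment so terminal gaps are free); `"pre-aligned"`
#' expects equal-length strings.
#'
#' @param a,b Nucleotide sequences.
#' @param mode `"global-align"` or `"pre-aligned"`.
#' @param include_end_gaps Count terminal-overhang columns in the
#'   denominator (default `FALSE`).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return Percent identity in \[0, 100\].
#' @export
#' @examples
#' percent_identity("ACGT", "ACGA", mode = "pre-aligned")  # 75
percent_identity <- function(a, b, mode = c("global-align", "pre-aligned"),
                             include_end_gaps = FALSE,
                             match = 1, mismatch = -1,
                             gap_open = 2, gap_extend = 0.5) {
  mode <- match.arg(mode)
  if (!nchar(a) || !nchar(b))
    abort_lgtree("empty sequence", "lgtree_arg_error")
  if (mode == "global-align") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
      type = if (include_end_gaps) "global" else "overlap",
      substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    sa <- as.character(Biostrings::alignedPattern(aln))
    sb <- as.character(Biostrings::alignedSubject(aln))
  } else {
    sa <- toupper(a); sb <- toupper(b)
    if (nchar(sa) != nchar(sb))
      abort_lgtree("pre-aligned mode needs equal-length sequences",
                   "lgtree_validation_error")
  }
  va <- strsplit(sa, "")[[1]]
  vb <- strsplit(sb, "")[[1]]
  keep <- !(va == "-" & vb == "-")
  if (!include_end_gaps && mode == "pre-aligned") {
    # strip terminal-overhang columns (gap at either end of either sequence)
    keep <- keep & !.end_gap_mask(va) & !.end_gap_mask(vb)
  }
  va <- va[keep]; vb <- vb[keep]
  if (!length(va))
    abort_lgtree("no aligned columns to compare", "lgtree_undefined_error")
  100 * sum(va == vb) / length(va)
}

.end_gap_mask <- function(v) {
  non_gap <- which(v != "-")
  mask <- rep(FALSE, length(v))
  if (!length(non_gap)) return(!mask)
  if (non_gap[1] > 1) mask[seq_len(non_gap[1] - 1)] <- TRUE
  if (non_gap[length(non_gap)] < length(v))
    mask[(non_gap[length(non_gap)] + 1):length(v)] <- TRUE
  mask
}
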