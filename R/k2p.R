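.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

as_char_alignment <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    return(toupper(x))
  }
  if (is.character(x)) {
    seqs <- toupper(x)
    if (length(unique(nchar(seqs))) != 1)
      abort_lgtree("aligned sequences must have equal length",
                   "lgtree_validation_error")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
    return(m)
  }
  abort_lgtree("unsupported alignment representation", "lgtree_arg_error")
}

#' Read an aligned FASTA file into a character matrix
#'
#' @param path Path to an aligned (equal-length) nucleotide FASTA file.
#' @return Character matrix, one row per sequence, uppercase.
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(toupper(as.character(ss)), names(ss))
  as_char_alignment(seqs)
}

#' Write sequences as FASTA
#' @param seqs Named character vector or character matrix (rows = sequences).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.matrix(seqs)) seqs <- setNames(apply(seqs, 1, paste, collapse = ""),
                                        rownames(seqs))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# P (transition), Q (transversion) proportions and compared-site count for an
# aligned pair; sites with a gap/ambiguity in either sequence are excluded.
pair_pq <- function(a, b) {
  if (length(a) != length(b))
    abort_lgtree("sequences differ in aligned length",
                 "lgtree_validation_error")
  ok <- a %in% .BASES & b %in% .BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0)
    return(list(P = NA_real_, Q = NA_real_, n = 0L))
  diff <- a != b
  ts <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n = n)
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' Computes `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, the K2P estimate
#' of substitutions per site, where `P` is the proportion of compared sites
#' showing a transition difference and `Q` the proportion showing a
#' transversion difference.
#'
#' @param P,Q Transition and transversion difference proportions.
#' @return Non-negative distance in substitutions/site; 0 iff `P = Q = 0`.
#'   Outside the defined domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) an
#'   explicit saturation error is raised rather than returning `Inf`/`NaN`.
#' @export
#' @examples
#' k2p_from_pq(0.1, 0)   # -0.5 * log(0.8)
k2p_from_pq <- function(P, Q) {
  stopifnot(is.numeric(P), is.numeric(Q), P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    abort_lgtree(
      sprintf("K2P saturation: P=%.4g Q=%.4g outside the defined domain",
              P, Q),
      "lgtree_saturation_error")
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or ambiguity code are excluded
#' (pairwise deletion).
#'
#' @param a,b Aligned nucleotide sequences (strings or character vectors of
#'   equal length).
#' @return Distance in substitutions/site.
#' @export
k2p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(toupper(b), "")[[1]]
  pq <- pair_pq(toupper(a), toupper(b))
  if (pq$n == 0)
    abort_lgtree("no comparable sites between the two sequences",
                 "lgtree_undefined_distance")
  k2p_from_pq(pq$P, pq$Q)
}

#' Pairwise K2P distance matrix from an alignment
#'
#' @param aln Character matrix (rows = taxa) or named character vector of
#'   equal-length sequences.
#' @param deletion `"pairwise"` (default; gap/ambiguous sites dropped per
#'   pair) or `"complete"` (columns containing any gap/ambiguity dropped for
#'   all pairs).
#' @return Symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @export
k2p_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- as_char_alignment(aln)
  if (deletion == "complete") {
    keep <- apply(m, 2, function(col) all(col %in% .BASES))
    if (!any(keep))
      abort_lgtree("complete deletion removed every column",
                   "lgtree_undefined_distance")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pq <- pair_pq(m[i, ], m[j, ])
      if (pq$n == 0)
        abort_lgtree(
          sprintf("no comparable sites between %s and %s",
                  rownames(m)[i], rownames(m)[j]),
          "lgtree_undefined_distance")
      d[i, j] <- d[j, i] <- k2p_from_pq(pq$P, pq$Q)
    }
  }
  d
}
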