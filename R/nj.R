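#' Neighbor-joining tree construction
#'
#' Saitou & Nei's agglomerative algorithm. On an additive distance matrix the
#' reconstructed unrooted tree reproduces every leaf-to-leaf path length
#' exactly. Output is deterministic: ties in the Q criterion are broken by the
#' lexicographically smallest pair of cluster names (a cluster is named by the
#' smallest leaf label it contains).
#'
#' @param dm Symmetric distance matrix with taxon dimnames (or a `dist`).
#' @param clamp_negative Clamp negative branch lengths to zero, transferring
#'   the deficit to the sister edge (default); `FALSE` preserves raw values.
#' @return An unrooted `phylo` tree over all taxa.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(d)
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (anyNA(dm) || any(!is.finite(dm)))
    abort_lgtree("distance matrix contains NA/NaN/Inf", "lgtree_arg_error")
  n <- nrow(dm)
  if (n < 3)
    abort_lgtree("neighbor joining needs >= 3 taxa", "lgtree_arg_error")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))

  d <- dm
  # active clusters: Newick fragment + tie-break name (smallest leaf label)
  frag <- labels
  cname <- labels
  fmt <- function(x) sprintf("%.15g", x)

  join_lengths <- function(bi, bj) {
    if (clamp_negative) {
      if (bi < 0) { bj <- bj + bi; bi <- 0 }
      if (bj < 0) { bi <- bi + bj; bj <- 0 }
      bi <- max(bi, 0); bj <- max(bj, 0)
    }
    c(bi, bj)
  }

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(cname[ij[1]], cname[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    b <- join_lengths(bi, bj)

    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(b[1]), frag[j], fmt(b[2]))
    newname <- min(cname[i], cname[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    d <- d2
    frag <- c(frag[keep], newfrag)
    cname <- c(cname[keep], newname)
  }

  # final three clusters join at the basal trifurcation
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clamp_negative) { ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0) }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], fmt(ba), frag[2], fmt(bb), frag[3], fmt(bc))
  ape::read.tree(text = newick)
}
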