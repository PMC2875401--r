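test_that("gc_content handles plain cases, ambiguity, and degenerate input", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 50)
  # ambiguity codes leave numerator and denominator
  expect_equal(gc_content("ACGTNNRY"), 50)
  expect_error(gc_content("NNNN"), class = "lgtree_undefined_error")
  expect_error(gc_content(""), class = "lgtree_undefined_error")
})

test_that("gc_content is strand-symmetric (property)", {
  set.seed(4)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:300, 1),
                      replace = TRUE), collapse = "")
    expect_equal(gc_content(s), gc_content(reverse_complement(s)))
  }
})

test_that("codon_usage counts, normalizes, and guards reading frames", {
  cu <- codon_usage("ATGGCTTAA")
  expect_equal(unname(cu$counts["ATG"]), 1)
  expect_equal(unname(cu$counts["GCT"]), 1)
  expect_equal(sum(cu$counts), 2)
  expect_equal(unname(cu$freq[c("ATG", "GCT")]), c(0.5, 0.5))
  expect_equal(sum(cu$freq), 1, tolerance = 1e-9)

  # duplicating the CDS set leaves frequencies unchanged
  set.seed(8)
  cds <- vapply(1:5, function(i)
    paste(c("ATG", sample(sense_codons(), 40, replace = TRUE), "TAA"),
          collapse = ""), "")
  expect_equal(codon_usage(c(cds, cds))$freq, codon_usage(cds)$freq)

  expect_error(codon_usage("ATGG"), class = "lgtree_validation_error")
  expect_warning(out <- codon_usage(c(ok = "ATGGCTTAA", bad = "ATGTAAGCTTAA")),
                 "internal stop")
  expect_equal(out$n_cds, 1)
  expect_error(codon_usage("ATGTAAGCTTAA", on_internal_stop = "fail"),
               class = "lgtree_validation_error")
})

test_that("codon counts match an independent Biostrings tally", {
  set.seed(15)
  cds <- vapply(1:20, function(i)
    paste(c("ATG", sample(sense_codons(), sample(30:80, 1), replace = TRUE)),
          collapse = ""), "")
  cu <- codon_usage(cds)
  oracle <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(cds), step = 3))
  oracle <- oracle[names(cu$counts)]
  expect_equal(unname(cu$counts), unname(oracle))
})

test_that("usage_correlation reproduces the textbook formula", {
  mkcu <- function(freq) {
    structure(list(counts = freq, freq = freq, mode = "overall",
                   n_cds = 1L, n_codons = sum(freq)),
              class = "codon_usage")
  }
  set.seed(16)
  u <- runif(61); u <- u / sum(u)
  expect_equal(usage_correlation(mkcu(u), mkcu(u))$r, 1)
  expect_equal(usage_correlation(mkcu(u), mkcu(2 * u + 0.01))$r, 1)

  v <- u + rnorm(61, sd = 0.004)
  res <- usage_correlation(mkcu(u), mkcu(v))
  r_direct <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-10)
  t_direct <- r_direct * sqrt(59 / (1 - r_direct^2))
  expect_equal(res$p, 2 * pt(-abs(t_direct), 59), tolerance = 1e-12)
  expect_true(abs(res$r) <= 1)

  expect_error(usage_correlation(mkcu(rep(1 / 61, 61)), mkcu(u)),
               class = "lgtree_undefined_error")
  rs <- codon_usage("ATGGCTTAA", mode = "rscu")
  expect_error(usage_correlation(rs, mkcu(u)), class = "lgtree_arg_error")
})

test_that("rscu normalization scales within synonymous families", {
  # two codons of one family used 3:1
  cu <- codon_usage(paste(c("GCT", "GCT", "GCT", "GCA"), collapse = ""))
  expect_equal(unname(cu$freq[c("GCT", "GCA")]), c(0.75, 0.25))
  rs <- codon_usage(paste(c("GCT", "GCT", "GCT", "GCA"), collapse = ""),
                    mode = "rscu")
  # 4-codon alanine family: RSCU = count * 4 / total
  expect_equal(unname(rs$freq[c("GCT", "GCA", "GCC", "GCG")]),
               c(3, 1, 0, 0))
})

test_that("percent_identity covers both modes and conventions", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA", mode = "pre-aligned"), 75)

  # terminal overhangs excluded by default in pre-aligned mode
  expect_equal(percent_identity("--GTAC", "ACGTAC", mode = "pre-aligned"), 100)
  expect_equal(percent_identity("--GTAC", "ACGTAC", mode = "pre-aligned",
                                include_end_gaps = TRUE),
               100 * 4 / 6)
  # gap-gap columns never count
  expect_equal(percent_identity("A-CG", "A-CG", mode = "pre-aligned"), 100)

  # global alignment recovers identity across an indel
  a <- "ACGTACGTACGTACGT"
  b <- "ACGTACGACGTACGT"  # one T deleted
  pid <- percent_identity(a, b)
  expect_equal(pid, 100 * 15 / 16, tolerance = 1)

  expect_error(percent_identity("", "ACGT"), class = "lgtree_arg_error")
  expect_error(percent_identity("AC", "ACGT", mode = "pre-aligned"),
               class = "lgtree_validation_error")
})

test_that("percent_identity is symmetric (property)", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.08)), collapse = "")
    expect_equal(percent_identity(a, b, mode = "pre-aligned"),
                 percent_identity(b, a, mode = "pre-aligned"))
  }
})
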