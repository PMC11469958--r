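make_ac <- function(m, p, starts = NULL, chrom = "chr1") {
  n_genes <- nrow(m)
  coords <- data.frame(gene = paste0("g", seq_len(n_genes)), chrom = chrom,
                       start = starts %||% (seq_len(n_genes) * 5e4))
  allelic_counts(m, p, coords)
}

test_that("allelic count container validates its inputs", {
  m <- matrix(0L, 2, 3)
  expect_error(make_ac(m - 1L, m), "non-negative")
  expect_error(allelic_counts(m, matrix(0L, 3, 3),
                              data.frame(gene = c("a", "b"),
                                         chrom = "chr1", start = c(1, 2))))
  ac <- make_ac(m, m)
  expect_equal(dim(ac), c(2, 3))
})

test_that("cis and trans correlations separate coupled pairs", {
  panel <- generate_gene_panel(4, coupled_fraction = 0.5, seed = 41,
                               kon_range = c(0.3, 0.8),
                               ksyn_range = c(20, 80),
                               koff_range = c(20, 60))
  ac <- generate_count_matrix(panel, 2500, seed = 42)
  pr <- pairwise_correlations(ac)
  coupled <- pr[pr$gene_a == "g0001" & pr$gene_b == "g0002", ]
  expect_gt(coupled$corr_cis, coupled$corr_trans + 0.1)
  uncoupled <- pr[pr$gene_a == "g0003" & pr$gene_b == "g0004", ]
  expect_lt(abs(uncoupled$cis_minus_trans), 0.1)
})

test_that("allele relabelling of one gene negates the statistic exactly", {
  set.seed(43)
  m <- matrix(rpois(2 * 400, 2), 2, 400)
  p <- matrix(rpois(2 * 400, 2), 2, 400)
  ac <- make_ac(m, p)
  pr <- pairwise_correlations(ac)
  # swap alleles of gene 2
  m2 <- m; p2 <- p
  m2[2, ] <- p[2, ]; p2[2, ] <- m[2, ]
  pr_swap <- pairwise_correlations(make_ac(m2, p2))
  expect_equal(pr_swap$corr_cis, pr$corr_trans, tolerance = 1e-12)
  expect_equal(pr_swap$cis_minus_trans, -pr$cis_minus_trans,
               tolerance = 1e-12)
  expect_equal(pr_swap$corr_total, pr$corr_total, tolerance = 1e-12)
})

test_that("distance bins follow the megabase convention", {
  m <- matrix(rpois(5 * 100, 3), 5, 100)
  p <- matrix(rpois(5 * 100, 3), 5, 100)
  ac <- make_ac(m, p, starts = c(0, 5e4, 3e5, 1.2e6, 3.2e6))
  pr <- pairwise_correlations(ac)
  expect_identical(pr$bin[pr$gene_a == "g1" & pr$gene_b == "g2"], "<0.1")
  expect_identical(pr$bin[pr$gene_a == "g1" & pr$gene_b == "g3"], "<0.5")
  expect_identical(pr$bin[pr$gene_a == "g1" & pr$gene_b == "g4"], "<1.5")
  expect_identical(pr$bin[pr$gene_a == "g1" & pr$gene_b == "g5"], "<3.5")
  # beyond the last bin the pair is not reported
  far <- make_ac(m[1:2, ], p[1:2, ], starts = c(0, 5e6))
  expect_equal(nrow(pairwise_correlations(far)), 0)
  cmt <- cis_minus_trans(pr)
  expect_true(all(cmt$by_bin$n_pairs >= 1))
  expect_true(all(is.finite(cmt$by_bin$median)))
})

test_that("zero-variance genes are excluded with a counter", {
  m <- matrix(rpois(2 * 100, 2), 2, 100)
  m[2, ] <- 0L
  ac <- make_ac(m, m)
  pr <- pairwise_correlations(ac)
  expect_true(is.na(pr$corr_cis[1]))
  expect_equal(attr(pr, "n_undefined"), 1L)
})

test_that("contingency tests flag zero margins and detect coupling", {
  # all cells maternal-only for gene 1: zero paternal margin
  m <- matrix(rpois(2 * 200, 3), 2, 200)
  p <- matrix(rpois(2 * 200, 3), 2, 200)
  p[1, ] <- 0L
  ct <- contingency_tests(make_ac(m, p), "g1", "g2")
  expect_identical(ct$flag, "zero margin")
  expect_true(is.na(ct$chisq_p))

  # perfectly allele-coupled pair
  set.seed(44)
  allele <- stats::runif(400) < 0.5
  cnt <- 1L + stats::rpois(400, 2)
  m2 <- rbind(ifelse(allele, cnt, 0L), ifelse(allele, cnt, 0L))
  p2 <- rbind(ifelse(allele, 0L, cnt), ifelse(allele, 0L, cnt))
  ct2 <- contingency_tests(make_ac(m2, p2), "g1", "g2")
  expect_lt(ct2$fisher_p, 1e-10)
  expect_lt(ct2$chisq_p, 1e-10)
})

test_that("implantation raises detection power monotonically", {
  panel <- generate_gene_panel(8, seed = 45, kon_range = c(0.2, 0.6),
                               ksyn_range = c(20, 60),
                               koff_range = c(20, 60))
  ac <- generate_count_matrix(panel, 1500, seed = 46)
  pw <- implantation_power(ac, implant_fractions = c(0, 0.1), n_reps = 25,
                           seed = 47)
  expect_lt(pw$power[pw$fraction == 0], 0.25)
  expect_gt(pw$power[pw$fraction == 0.1],
            pw$power[pw$fraction == 0])
  # determinism
  pw2 <- implantation_power(ac, implant_fractions = c(0, 0.1), n_reps = 25,
                            seed = 47)
  expect_identical(pw, pw2)
})
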