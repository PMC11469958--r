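test_that("gene panels are seeded, ranged and reciprocally coupled", {
  expect_equal(nrow(generate_gene_panel(0)), 0)
  p1 <- generate_gene_panel(40, coupled_fraction = 0.5, seed = 3)
  p2 <- generate_gene_panel(40, coupled_fraction = 0.5, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1$k_syn >= 3 & p1$k_syn <= 200))
  expect_true(all(p1$k_on >= 1 / 24 & p1$k_on <= 1))
  expect_true(all(diff(p1$start) > 0))
  # coupling is reciprocal and shares the switching rates
  coupled <- p1[p1$coupled, ]
  for (g in seq_len(nrow(coupled))) {
    partner <- p1[p1$gene == coupled$partner[g], ]
    expect_identical(partner$partner, coupled$gene[g])
    expect_identical(partner$k_on, coupled$k_on[g])
    expect_identical(partner$k_off, coupled$k_off[g])
  }
  expect_error(generate_gene_panel(5, kon_range = c(-1, 2)), "range")
})

test_that("count matrices match analytic means and degenerate limits", {
  panel <- generate_gene_panel(3, seed = 5)
  panel$k_syn[2] <- 0
  ac <- generate_count_matrix(panel, 3000, seed = 6)
  expect_true(all(ac$maternal[2, ] == 0))
  expect_true(all(ac$paternal[2, ] == 0))
  for (g in c(1, 3)) {
    pp <- kinetic_params(panel$k_on[g], panel$k_off[g], panel$k_syn[g],
                         0.065)
    mu <- burstkin:::labelled_mean(pp, 2)
    se <- stats::sd(ac$maternal[g, ]) / sqrt(3000)
    expect_lt(abs(mean(ac$maternal[g, ]) - mu), 4 * se + 0.02)
  }
  # the two alleles of one gene are independent by construction
  r <- suppressWarnings(stats::cor(ac$maternal[1, ], ac$paternal[1, ],
                                   method = "spearman"))
  expect_lt(abs(r), 0.06)
})

test_that("molecule tables reproduce the conversion mixture rates", {
  panel <- generate_gene_panel(4, seed = 7)
  ac <- generate_count_matrix(panel, 300, seed = 8)
  model <- conversion_model(0.04, 0.002)
  mol <- generate_molecule_table(ac, model, seed = 9)
  expect_true(all(mol$n_converted <= mol$n_convertible))
  new_rate <- with(mol[mol$is_new_true, ],
                   sum(n_converted) / sum(n_convertible))
  old_rate <- with(mol[!mol$is_new_true, ],
                   sum(n_converted) / sum(n_convertible))
  se_new <- sqrt(0.04 * 0.96 / sum(mol$n_convertible[mol$is_new_true]))
  se_old <- sqrt(0.002 * 0.998 / sum(mol$n_convertible[!mol$is_new_true]))
  expect_lt(abs(new_rate - 0.04), 3 * se_new)
  expect_lt(abs(old_rate - 0.002), 3 * se_old)
  # allele labels are consistent with the count matrix totals
  new_m <- mol[mol$is_new_true & mol$allele_true == "maternal", ]
  tab <- table(new_m$gene)
  expect_equal(as.integer(tab[panel$gene]),
               as.integer(rowSums(ac$maternal)))
  # determinism
  mol2 <- generate_molecule_table(ac, model, seed = 9)
  expect_identical(mol, mol2)
})

test_that("round trip: pipeline recovers the generating conversion model", {
  panel <- generate_gene_panel(6, seed = 11)
  ac <- generate_count_matrix(panel, 400, seed = 12)
  mol <- generate_molecule_table(ac, conversion_model(0.04, 0.002),
                                 seed = 13)
  em <- em_conversion_rate(mol, pe = 0.002)
  expect_lt(abs(em$pc / 0.04 - 1), 0.1)
  expect_lt(abs(em$pi_new - mean(mol$is_new_true)), 0.05)
  calls <- classify_molecule(mol$n_convertible, mol$n_converted, em)
  fpr <- mean(calls[!mol$is_new_true] == "new")
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / sum(!mol$is_new_true)))
})
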