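test_that("maximum-likelihood fit improves on its initialisation", {
  tab <- shared_lookup()
  counts <- sample_counts(mid_grid_params(), 4000, seed = 7)
  st <- compute_summary_stats(counts)
  ini <- initialize_parameters(st, tab)
  expect_equal(ini$status, "ok")
  fit <- fit_mle(counts, ini$params, 2, 0.065,
                 bounds = burstkin:::fit_bounds_from_table(tab))
  expect_equal(fit$status, "ok")
  expect_gte(fit$logLik, fit$init_logLik)
  # the on-rate and the burst size are the identifiable quantities at this
  # cell number; both recover within a factor of two
  expect_lt(abs(log(fit$params$k_on / 0.8944)), log(2))
  expect_lt(abs(log((fit$params$k_syn / fit$params$k_off) /
                      (22.36 / 77.46))), log(2))
})

test_that("degenerate count vectors fail cleanly", {
  tab <- shared_lookup()
  fit <- fit_mle(rep(0L, 50), mid_grid_params(), 2, 0.065)
  expect_equal(fit$status, "failed")
  expect_match(fit$reason, "zero")
  g <- infer_gene(rep(0L, 50), tab, bootstrap = FALSE)
  expect_equal(g$status, "failed")
})

test_that("bootstrap is seed-deterministic and reports quartile structure", {
  tab <- shared_lookup()
  counts <- sample_counts(kinetic_params(0.6, 30, 25, 0.065), 400,
                          seed = 21)
  b1 <- bootstrap_gene(counts, tab, n_boot = 8, seed = 4)
  b2 <- bootstrap_gene(counts, tab, n_boot = 8, seed = 4)
  expect_identical(b1$quartiles, b2$quartiles)
  expect_identical(b1$robust, b2$robust)
  ok <- !is.na(b1$quartiles$q25)
  expect_true(all(b1$quartiles$q25[ok] <= b1$quartiles$q50[ok] + 1e-12))
  expect_true(all(b1$quartiles$q50[ok] <= b1$quartiles$q75[ok] + 1e-12))
  expect_gte(b1$fail_fraction, 0)
  expect_lte(b1$fail_fraction, 1)
})

test_that("robustness requires fewer than half of bootstraps failing", {
  tab <- shared_lookup()
  # a gene expressed in a single cell out of many: most resamples lose the
  # expressing cell or fall outside the interpolation domain
  counts <- c(rep(0L, 199), 2L)
  b <- bootstrap_gene(counts, tab, n_boot = 12, seed = 2)
  if (b$fail_fraction >= 0.5) {
    expect_false(any(b$robust))
  } else {
    succeed()
  }
})

test_that("full gene inference orchestrates all stages", {
  tab <- shared_lookup()
  counts <- sample_counts(kinetic_params(0.6, 30, 25, 0.065), 400,
                          seed = 21)
  g <- infer_gene(counts, tab, seed = 5, n_boot = 6, bootstrap = TRUE)
  expect_s3_class(g, "gene_inference")
  expect_equal(g$status, "ok")
  expect_s3_class(g$estimates, "kinetic_params")
  expect_s3_class(g$derived, "derived_kinetics")
  expect_equal(g$derived$burst_size,
               g$estimates$k_syn / g$estimates$k_off)
  expect_s3_class(g$bootstrap, "gene_bootstrap")

  row <- burstkin:::gene_inference_row(g, "geneA")
  expect_identical(row$gene, "geneA")
  expect_equal(row$k_on, g$estimates$k_on)
})

test_that("split-half partition is deterministic and correlations line up", {
  tab <- shared_lookup()
  panel <- generate_gene_panel(12, kon_range = c(0.2, 1.5),
                               ksyn_range = c(8, 60),
                               koff_range = c(10, 80), seed = 31)
  ac <- generate_count_matrix(panel, 600, seed = 32)
  mat <- ac$maternal + ac$paternal
  sh1 <- split_half_analysis(mat, tab, seed = 9)
  sh2 <- split_half_analysis(mat, tab, seed = 9)
  expect_identical(sh1$cells, sh2$cells)
  expect_identical(sh1$correlation, sh2$correlation)
  expect_equal(length(intersect(sh1$cells$half1, sh1$cells$half2)), 0)
  expect_equal(sort(c(sh1$cells$half1, sh1$cells$half2)), seq_len(600))
  expect_identical(dim(sh1$correlation), dim(sh1$p_adjusted))
  # the on-rate is reproducible across independent halves
  expect_gt(sh1$correlation["k_on", "k_on"], 0.5)
  # measured fraction expressing is highly reproducible
  expect_gt(sh1$correlation["frac_expressing", "frac_expressing"], 0.8)
})

test_that("inference table export round-trips", {
  tab <- shared_lookup()
  counts <- rbind(g1 = sample_counts(kinetic_params(0.6, 30, 25, 0.065),
                                     200, seed = 41),
                  g2 = rep(0L, 200))
  res <- infer_genes(counts, tab, bootstrap = FALSE)
  expect_equal(nrow(res), 2)
  expect_equal(res$status[2], "failed")
  path <- tempfile(fileext = ".tsv")
  write_inference_tsv(res, path, seed = 1)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  expect_equal(back$gene, res$gene)
  expect_equal(back$k_on, res$k_on, tolerance = 1e-6)
  header <- readLines(path, n = 4)
  expect_true(any(grepl("^# burstkin", header)))
  expect_true(any(grepl("^# seed: 1", header)))
})
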