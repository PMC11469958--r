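test_that("read-group merging reproduces single- and multi-read consensus", {
  one <- merge_read_group(data.frame(read = "r1", pos = 10L, base = "T",
                                     qual = 30))
  expect_identical(one$base, "T")
  expect_equal(one$qual, 30, tolerance = 1e-9)

  two <- merge_read_group(data.frame(read = c("r1", "r2"), pos = 10L,
                                     base = "T", qual = 30))
  expect_identical(two$base, "T")
  expect_equal(two$qual, 64.8, tolerance = 0.05)

  tie <- merge_read_group(data.frame(read = c("r1", "r2"), pos = 10L,
                                     base = c("T", "C"), qual = 30))
  expect_identical(tie$base, "N")

  # a sequencer N adds no information
  with_n <- merge_read_group(data.frame(read = c("r1", "r2"), pos = 10L,
                                        base = c("T", "N"),
                                        qual = c(30, 2)))
  expect_identical(with_n$base, "T")
  expect_equal(with_n$qual, 30, tolerance = 1e-9)

  # merged Phred capped at 93
  many <- merge_read_group(data.frame(read = paste0("r", 1:12), pos = 1L,
                                      base = "G", qual = 40))
  expect_equal(many$qual, 93)
  expect_error(merge_read_group(NULL), "empty")
})

test_that("artifact masking flags only recurrently mismatched positions", {
  # background ~2%; one implanted SNP-like position
  ps <- data.frame(pos = 1:101,
                   n_molecules = 50L,
                   n_mismatch = c(rep(0L, 40), rep(1L, 60), 30L))
  out <- mask_artifact_positions(ps, alpha = 0.05)
  expect_identical(attr(out, "masked_positions"), 101L)
  # zero-mismatch positions can never be masked
  expect_true(all(!out$masked[out$n_mismatch == 0]))
  # Bonferroni monotonicity: more positions tested can only unmask
  ps2 <- rbind(ps, data.frame(pos = 102:202, n_molecules = 50L,
                              n_mismatch = rep(0:1, length.out = 101)))
  out2 <- mask_artifact_positions(ps2, alpha = 0.05)
  expect_true(all(out2$pos[out2$masked] %in% out$pos[out$masked]))
})

test_that("error rate averages the complementary mismatch rates", {
  mol <- data.frame(n_c_sites = c(500, 500), n_c_to_t = c(1, 1),
                    n_g_sites = c(250, 250), n_g_to_a = c(1, 1))
  expect_equal(estimate_error_rate(mol), (0.002 + 0.004) / 2)
  zero <- data.frame(n_c_sites = 100, n_c_to_t = 0, n_g_sites = 100,
                     n_g_to_a = 0)
  pe0 <- estimate_error_rate(zero)
  expect_equal(as.numeric(pe0), 0)
  expect_true(attr(pe0, "degenerate"))
  expect_error(estimate_error_rate(data.frame(n_c_sites = 0, n_c_to_t = 0,
                                              n_g_sites = 0,
                                              n_g_to_a = 0)), "no covered")
  # signal-to-noise scale of the fibroblast data
  expect_equal(conversion_model(0.06, 0.003)$signal_to_noise, 20)
})

test_that("EM recovers the conversion mixture from simulated molecules", {
  set.seed(8)
  n_mol <- 2000
  is_new <- stats::runif(n_mol) < 0.3
  n_conv <- rep(20L, n_mol)
  k <- stats::rbinom(n_mol, n_conv, ifelse(is_new, 0.05, 0.001))
  mol <- data.frame(n_convertible = n_conv, n_converted = k)
  em <- em_conversion_rate(mol, pe = 0.001)
  expect_true(em$converged)
  expect_true(is.na(em$flag))
  expect_lt(abs(em$pc / 0.05 - 1), 0.1)
  expect_lt(abs(em$pi_new - 0.3), 0.05)
  expect_true(all(diff(em$loglik) > -1e-6))

  # degenerate mixture: pc equals pe
  k_same <- stats::rbinom(n_mol, n_conv, 0.002)
  em_deg <- em_conversion_rate(data.frame(n_convertible = n_conv,
                                          n_converted = k_same),
                               pe = 0.002)
  expect_false(is.na(em_deg$flag))
  expect_error(em_conversion_rate(mol[1:5, ], pe = 0.001), "at least 10")
})

test_that("LRT classification is monotone with exact trivial cases", {
  model <- conversion_model(0.05, 0.001)
  expect_identical(classify_molecule(20, 0, model), "old")
  expect_identical(classify_molecule(20, 3, model), "new")
  expect_identical(classify_molecule(0, 0, model), "uncalled")
  # monotone in the conversion count at fixed length
  calls <- classify_molecule(rep(30, 31), 0:30, model)
  first_new <- match("new", calls)
  expect_true(all(calls[first_new:31] == "new"))
  expect_true(all(calls[seq_len(first_new - 1)] == "old"))
  expect_error(classify_molecule(5, 7, model), "exceeds")
})

test_that("detection power equals brute-force enumeration", {
  model <- conversion_model(0.06, 0.003)
  expect_equal(detection_power(0, model), 0)
  pw <- detection_power(c(5, 20, 60, 100, 200), model)
  expect_true(all(diff(pw) >= 0))
  # independent enumeration oracle at n = 100: classify every possible
  # conversion count and sum new-call probabilities under pc
  n <- 100
  calls <- classify_molecule(rep(n, n + 1), 0:n, model)
  brute <- sum(stats::dbinom(0:n, n, model$pc)[calls == "new"])
  expect_equal(detection_power(n, model), brute, tolerance = 1e-12)
})

test_that("genotyping follows the exclusive-evidence rule", {
  expect_identical(genotype_molecule(2, 0), "maternal")
  expect_identical(genotype_molecule(0, 3), "paternal")
  expect_identical(genotype_molecule(1, 1), "unassigned")
  expect_identical(genotype_molecule(0, 0), "unassigned")
  expect_identical(genotype_molecule(c(1, 0), c(0, 0)),
                   c("maternal", "unassigned"))
})

test_that("sample QC keeps cells strictly above the threshold", {
  totals <- c(a = 4000, b = 4001, c = 12000, d = 2700)
  expect_identical(sample_qc_filter(totals, "fibroblast"), c("b", "c"))
  expect_identical(sample_qc_filter(totals, "k562"), c("a", "b", "c"))
  expect_identical(sample_qc_filter(unname(totals), 4000), c(2L, 3L))
})

test_that("read-level calling drops variant-free reads and applies the LRT", {
  model <- conversion_model(0.06, 0.003)
  reads <- data.frame(cell = "c1", gene = "g1",
                      n_maternal = c(2, 0, 0, 1),
                      n_paternal = c(0, 0, 2, 1),
                      n_convertible = c(15, 15, 15, 15),
                      n_converted = c(1, 1, 5, 0))
  out <- call_reads(reads, model)
  expect_equal(nrow(out), 3)  # the variant-free read is removed
  expect_identical(out$allele, c("maternal", "paternal", "unassigned"))
  # exact LRT outcomes: P(K >= 1 | 15, 0.003) = 0.044 < 0.05 so one
  # conversion over 15 sites already rejects the old hypothesis
  expect_equal(stats::pbinom(0, 15, 0.003, lower.tail = FALSE), 0.044,
               tolerance = 1e-2)
  expect_identical(out$temporal_call, c("new", "new", "old"))
  empty <- call_reads(reads[0, ], model)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("allele", "temporal_call") %in% names(empty)))
})
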