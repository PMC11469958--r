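test_that("published grid axes are log-equidistant with ~1.15x steps", {
  spec <- lookup_grid_spec()
  expect_length(spec$kon, 73)
  expect_length(spec$ksyn, 38)
  expect_length(spec$koff, 55)
  expect_equal(range(spec$kon), c(0.002, 50))
  expect_equal(range(spec$ksyn), c(1, 200))
  expect_equal(range(spec$koff), c(0.25, 500))
  for (ax in spec[c("kon", "ksyn", "koff")]) {
    ratios <- ax[-1] / ax[-length(ax)]
    expect_lt(diff(range(ratios)), 1e-12)  # constant consecutive ratio
  }
  expect_equal(spec$kon[2] / spec$kon[1], (50 / 0.002)^(1 / 72))
  expect_equal(round(spec$kon[2] / spec$kon[1], 2), 1.15)
  expect_equal(round(spec$ksyn[2] / spec$ksyn[1], 2), 1.15)
  expect_equal(round(spec$koff[2] / spec$koff[1], 2), 1.15)
  expect_identical(73L * 38L * 55L, 152570L)
})

test_that("lookup table construction is deterministic and serializable", {
  grid <- lookup_grid_spec(n_kon = 4, kon_range = c(0.2, 2),
                           n_ksyn = 3, ksyn_range = c(5, 50),
                           n_koff = 3, koff_range = c(10, 100))
  t1 <- build_lookup_table(grid, cells_per_combo = 200, seed = 5,
                           stats_mode = "sampled")
  t2 <- build_lookup_table(grid, cells_per_combo = 200, seed = 5,
                           stats_mode = "sampled")
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- build_lookup_table(grid, cells_per_combo = 200, seed = 6,
                           stats_mode = "sampled")
  expect_false(identical(t1$frac_expressing, t3$frac_expressing))

  # exact mode carries no Monte-Carlo noise at all
  e1 <- build_lookup_table(grid, seed = 5)
  e2 <- build_lookup_table(grid, seed = 99)
  expect_identical(e1$cv_expressing, e2$cv_expressing)

  path <- tempfile(fileext = ".tsv")
  save_lookup_table(t1, path)
  t1b <- load_lookup_table(path)
  expect_identical(t1b$frac_expressing, t1$frac_expressing)
  expect_identical(t1b$cv_expressing, t1$cv_expressing)
  expect_equal(attr(t1b, "axes")$kon, attr(t1, "axes")$kon)
  expect_identical(attr(t1b, "k_d"), attr(t1, "k_d"))
  expect_identical(attr(t1b, "seed"), attr(t1, "seed"))
})

test_that("initialisation returns stored parameters for stored statistics", {
  tab <- tiny_lookup()
  interior <- which(tab$in_domain & tab$i > 1 & tab$i < max(tab$i) &
                      tab$j > 1 & tab$j < max(tab$j) &
                      tab$k > 1 & tab$k < max(tab$k))
  r <- interior[1]
  st <- structure(list(frac_expressing = tab$frac_expressing[r],
                       mean_expressing = tab$mean_expressing[r],
                       cv_expressing = tab$cv_expressing[r],
                       n_cells = 1000L, n_expressing = 500L,
                       defined = TRUE), class = "summary_stats")
  ini <- initialize_parameters(st, tab)
  expect_equal(ini$status, "ok")
  expect_equal(ini$method, "exact")
  expect_equal(ini$params$k_on, tab$k_on[r])
  expect_equal(ini$params$k_syn, tab$k_syn[r])
  expect_equal(ini$params$k_off, tab$k_off[r])
})

test_that("initialisation excludes out-of-domain and boundary statistics", {
  tab <- tiny_lookup()
  # overall mean expression outside the published 0.01-350 interval
  st_lo <- structure(list(frac_expressing = 0.001, mean_expressing = 1,
                          cv_expressing = 0.5, n_cells = 1000L,
                          n_expressing = 1L, defined = TRUE),
                     class = "summary_stats")
  ini <- initialize_parameters(st_lo, tab)
  expect_equal(ini$status, "excluded")
  expect_match(ini$reason, "outside")

  st_hi <- structure(list(frac_expressing = 1, mean_expressing = 500,
                          cv_expressing = 0.5, n_cells = 1000L,
                          n_expressing = 1000L, defined = TRUE),
                     class = "summary_stats")
  expect_equal(initialize_parameters(st_hi, tab)$status, "excluded")

  # no expressing cells
  und <- compute_summary_stats(rep(0L, 10))
  expect_equal(initialize_parameters(und, tab)$status, "excluded")

  # statistics of a boundary entry identify boundary parameters
  bnd <- which(tab$in_domain & tab$i == 1)[1]
  st_b <- structure(list(frac_expressing = tab$frac_expressing[bnd],
                         mean_expressing = tab$mean_expressing[bnd],
                         cv_expressing = tab$cv_expressing[bnd],
                         n_cells = 1000L, n_expressing = 500L,
                         defined = TRUE), class = "summary_stats")
  expect_equal(initialize_parameters(st_b, tab)$status,
               "boundary-excluded")
})

test_that("statistics outside the hull fall back to the nearest entry", {
  tab <- tiny_lookup()
  # implausible combination far from every stored entry
  st <- structure(list(frac_expressing = 0.35, mean_expressing = 900 / 35,
                       cv_expressing = 12, n_cells = 1000L,
                       n_expressing = 350L, defined = TRUE),
                  class = "summary_stats")
  ini <- initialize_parameters(st, tab)
  expect_equal(ini$method, "nearest")
  if (ini$status == "ok") {
    hit <- which(tab$k_on == ini$params$k_on &
                   tab$k_syn == ini$params$k_syn &
                   tab$k_off == ini$params$k_off)
    expect_length(hit, 1)
  }
})
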