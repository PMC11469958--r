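test_that("kinetic parameter validation and derived quantities", {
  expect_error(kinetic_params(-1, 1, 1, 0.065), "finite and non-negative")
  expect_error(kinetic_params(NA, 1, 1, 0.065), "finite and non-negative")
  expect_error(kinetic_params(Inf, 1, 1, 0.065), "finite and non-negative")

  d <- derived_kinetics(kinetic_params(1, 1, 10, 0.065))
  expect_equal(d$occupancy, 0.5)
  expect_equal(d$burst_size, 10)
  expect_equal(d$burst_frequency, 0.5)
  expect_equal(d$expression_rate, 5)

  d2 <- derived_kinetics(kinetic_params(0.2, 77.46, 22.36, 0.065))
  expect_equal(d2$occupancy, 0.2 / 77.66, tolerance = 1e-6)
  expect_equal(d2$occupancy, 0.0025753, tolerance = 1e-4)
  expect_equal(d2$burst_size, 0.28866, tolerance = 1e-4)
  expect_equal(d2$burst_frequency, 0.199485, tolerance = 1e-5)
  expect_equal(d2$expression_rate, 0.057584, tolerance = 1e-4)

  # occupancy 0.5 whenever the switching rates are equal
  for (k in c(0.01, 1, 250)) {
    expect_equal(derived_kinetics(kinetic_params(k, k, 5, 0.1))$occupancy,
                 0.5)
  }
  # burst frequency never exceeds either switching rate
  set.seed(1)
  for (i in 1:20) {
    p <- kinetic_params(runif(1, 0.01, 10), runif(1, 0.01, 100),
                        runif(1, 1, 100), 0.065)
    bf <- derived_kinetics(p)$burst_frequency
    expect_lte(bf, min(p$k_on, p$k_off) + 1e-12)
  }
  expect_error(derived_kinetics(kinetic_params(1, 0, 10, 0.065)),
               "k_off > 0")
})

test_that("transient PMF degenerate limits are point masses at zero", {
  expect_equal(transient_pmf(kinetic_params(1, 5, 0, 0.065), 2)$probs, 1)
  expect_equal(transient_pmf(kinetic_params(1, 5, 20, 0.065), 0)$probs, 1)
  expect_equal(transient_pmf(kinetic_params(0, 5, 20, 0.065), 2)$probs, 1)
})

test_that("transient PMF input validation", {
  expect_error(transient_pmf(kinetic_params(1, 5, 20, 0.065), 2,
                             tail_eps = 1e-3), "tail_eps")
  expect_error(transient_pmf(kinetic_params(1, 5, 20, 0.065), 2,
                             tail_eps = 0), "tail_eps")
  expect_error(transient_pmf(kinetic_params(1, 5, 20, 0.065), -1))
})

test_that("always-on limit reduces to a Poisson birth-death distribution", {
  # k_off = 0: gene permanently on; labelled counts are Poisson with mean
  # k_syn (1 - exp(-k_d t)) / k_d
  pmf <- transient_pmf(kinetic_params(1, 0, 10, 0.065), 2)
  mu <- 10 * (1 - exp(-0.13)) / 0.065
  expect_equal(mu, 18.745, tolerance = 1e-3)
  n <- seq_along(pmf$probs) - 1
  expect_lt(max(abs(pmf$probs - stats::dpois(n, mu))), 1e-9)
})

test_that("transient PMF agrees with the master-equation oracle", {
  pp <- kinetic_params(1, 5, 20, 0.065)
  pmf <- transient_pmf(pp, 2)
  or <- cme_oracle_pmf(pp, 2, n_max = length(pmf$probs) + 40)
  n <- seq_along(pmf$probs)
  expect_lt(max(abs(pmf$probs - or$probs[n])), 1e-8)

  # a bursty corner case
  pp2 <- kinetic_params(0.1, 40, 60, 0.065)
  pmf2 <- transient_pmf(pp2, 2)
  or2 <- cme_oracle_pmf(pp2, 2, n_max = length(pmf2$probs) + 60)
  expect_lt(max(abs(pmf2$probs - or2$probs[seq_along(pmf2$probs)])), 1e-8)
})

test_that("oracle PMF satisfies the analytic first moment", {
  pp <- kinetic_params(1, 5, 20, 0.065)
  or <- cme_oracle_pmf(pp, 2, n_max = 90)
  mu <- 20 * (1 / 6) * (1 - exp(-0.13)) / 0.065
  expect_equal(sum(or$probs * (seq_along(or$probs) - 1)), mu,
               tolerance = 1e-8)
  expect_equal(cme_oracle_pmf(kinetic_params(1, 5, 0, 0.065), 2,
                              n_max = 4)$probs[1], 1, tolerance = 1e-12)
})

test_that("PMF normalization and first moment hold across parameter space", {
  set.seed(42)
  for (i in 1:8) {
    pp <- kinetic_params(exp(runif(1, log(0.01), log(20))),
                         exp(runif(1, log(1), log(300))),
                         exp(runif(1, log(2), log(150))), 0.065)
    pmf <- transient_pmf(pp, 2)
    expect_lt(abs(1 - sum(pmf$probs)), 1e-10)
    expect_true(all(pmf$probs >= 0))
    full <- burstkin:::pmf_vector(pp, 2)
    mu <- burstkin:::labelled_mean(pp, 2)
    expect_equal(sum(full * (seq_along(full) - 1)), mu,
                 tolerance = 1e-6)
  }
})

test_that("steady-state PMF matches its closed-form limits", {
  expect_equal(steady_state_pmf(kinetic_params(1, 5, 0, 0.065))$probs, 1)
  expect_error(steady_state_pmf(kinetic_params(1, 5, 20, 0)), "k_d")
  # always-on: Poisson(k_syn / k_d)
  ss <- steady_state_pmf(kinetic_params(1, 0, 2, 0.1))
  n <- seq_along(ss$probs) - 1
  expect_lt(max(abs(ss$probs - stats::dpois(n, 20))), 1e-12)
})

test_that("transient PMF converges to the stationary Poisson-beta law", {
  pp <- mid_grid_params()
  tr <- transient_pmf(pp, 1000)
  ss <- steady_state_pmf(pp)
  n <- seq_len(min(length(tr$probs), length(ss$probs)))
  expect_lt(max(abs(tr$probs[n] - ss$probs[n])), 1e-6)
})

test_that("log-likelihood behaves as a sum of per-cell log probabilities", {
  pp <- kinetic_params(1, 5, 20, 0.065)
  expect_equal(log_likelihood(c(0, 0, 0), kinetic_params(1, 5, 0, 0.065),
                              2), 0)
  pmf <- transient_pmf(pp, 2)
  expect_equal(log_likelihood(3, pp, 2), log(pmf$probs[4]),
               tolerance = 1e-9)
  a <- c(0, 1, 5)
  b <- c(2, 2, 7, 0)
  expect_equal(log_likelihood(c(a, b), pp, 2),
               log_likelihood(a, pp, 2) + log_likelihood(b, pp, 2),
               tolerance = 1e-9)
  expect_error(log_likelihood(c(-1, 2), pp, 2), "non-negative")
  expect_error(log_likelihood(integer(0), pp, 2), "non-empty")
  # impossible counts under a degenerate model flag -Inf
  ll <- log_likelihood(c(0, 4), kinetic_params(1, 5, 0, 0.065), 2)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "zero_prob"))
})

test_that("PMF TSV export is a valid two-column table", {
  pmf <- transient_pmf(kinetic_params(1, 5, 20, 0.065), 2)
  path <- tempfile(fileext = ".tsv")
  write_pmf_tsv(pmf, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  expect_identical(names(tab), c("count", "probability"))
  expect_equal(tab$count, seq_along(pmf$probs) - 1L)
  expect_equal(tab$probability, pmf$probs, tolerance = 1e-15)
  expect_lt(abs(1 - sum(tab$probability)), 1e-10)
})
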