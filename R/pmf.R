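#' @useDynLib burstkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_pulse_pmf <- function(probs, params, label_time, tail_eps, method) {
  structure(list(probs = probs, params = params, label_time = label_time,
                 tail_eps = tail_eps, method = method),
            class = "pulse_pmf")
}

#' @export
print.pulse_pmf <- function(x, ...) {
  cat(sprintf("pulse PMF (%s): support 0..%d, t = %g h, 1 - sum = %.3g\n",
              x$method, length(x$probs) - 1L, x$label_time,
              1 - sum(x$probs)))
  invisible(x)
}

#' @export
mean.pulse_pmf <- function(x, ...) {
  sum(x$probs * seq_along(x$probs) - x$probs)
}

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(max(2, n))))

# analytic first moment of the labelled-count distribution
labelled_mean <- function(params, label_time) {
  occ <- occupancy(params)
  if (params$k_d > 0) {
    params$k_syn * occ * (1 - exp(-params$k_d * label_time)) / params$k_d
  } else {
    params$k_syn * occ * label_time
  }
}

# crude upper bound on the Fano factor, only used to size the FFT grid
labelled_fano_bound <- function(params) {
  with(params, 1 + (k_off / (k_on + k_off)) *
         k_syn / (k_on + k_off + k_d + 1e-12))
}

# full (untruncated) probability vector from the PGF engine, covering at
# least counts 0..n_min; escalates grid size / tolerance until the upper
# tail is resolved and no material negative entries remain.  Tail adequacy
# is checked both directly (mass in the last eighth of the grid) and via
# the analytic first moment: aliased tail mass folds back to low counts and
# depresses the mean by roughly (tail mass) * m, so agreement of the
# computed mean with the closed-form mean certifies the truncation.
pmf_vector <- function(params, label_time, n_min = 0L, tol = 1e-14,
                       max_m = 2^17, tail_floor = 1e-12) {
  mu <- labelled_mean(params, label_time)
  sd_b <- sqrt(max(mu, 1e-12) * labelled_fano_bound(params))
  burst_tail <- with(params, (k_off / (k_on + k_off)) *
                       k_syn / (k_off + k_d + 1))
  # tail margins scale with how deeply the tail must be resolved
  sc <- log(tail_floor) / log(1e-12)
  m <- next_pow2(max(16, n_min + 2,
                     ceiling(mu + (4 + 8 * sc) * sd_b +
                               30 * sc * burst_tail + 30)))
  repeat {
    p <- .pgf_pmf_engine(params$k_on, params$k_off, params$k_syn,
                         params$k_d, label_time, m, tol, 46)
    neg <- min(p)
    if (neg < -max(1e-9, 100 * tol)) {
      if (tol > 1e-15) { tol <- tol / 10; next }
      stop("transient PMF evaluation failed to converge (negative mass ",
           signif(neg, 3), ")")
    }
    p[p < 0] <- 0
    tail_mass <- sum(p[seq.int(floor(7 * m / 8) + 1L, m)])
    mean_ok <- abs(sum(p * (seq_along(p) - 1)) - mu) <=
      max(1e-5 * mu * sqrt(sc), 10 * m * tail_floor, 1e-8)
    if (tail_mass < max(tail_floor, 100 * tol) && mean_ok) return(p)
    if (m >= max_m) {
      stop("transient PMF evaluation failed to converge (support > ",
           max_m, ")")
    }
    m <- m * 2L
  }
}

#' Transient PMF of labelled-RNA counts
#'
#' Probability distribution of the number of labelled (new) RNA molecules
#' after a labelling window of `label_time` hours, under the two-state
#' telegraph model: the promoter starts at its stationary distribution with
#' zero labelled molecules, synthesis occurs at `k_syn` only while on, and
#' labelled molecules degrade at `k_d` throughout the window.
#'
#' The PMF is obtained from the probability generating function, which solves
#' a 2x2 linear ODE along the characteristics of the labelled-count master
#' equation; generating-function values on the unit circle are inverted by
#' FFT. The support is extended adaptively until the truncated tail mass is
#' below `tail_eps`.
#'
#' @param params A [kinetic_params()] object.
#' @param label_time Labelling time in hours (>= 0).
#' @param tail_eps Truncation tolerance for the upper tail, in (0, 1e-4].
#' @return A `pulse_pmf` object whose `probs` element is the probability
#'   vector for counts `0..n_max`.
#' @examples
#' pmf <- transient_pmf(kinetic_params(1, 5, 20, 0.065), label_time = 2)
#' sum(pmf$probs)
#' @export
transient_pmf <- function(params, label_time, tail_eps = 1e-10) {
  params <- as_kinetic_params(params)
  stopifnot(is.numeric(label_time), length(label_time) == 1L,
            is.finite(label_time), label_time >= 0)
  if (tail_eps <= 0 || tail_eps > 1e-4) {
    stop("tail_eps must be in (0, 1e-4]")
  }
  if (params$k_syn == 0 || label_time == 0 || params$k_on == 0) {
    return(new_pulse_pmf(1, params, label_time, tail_eps, "degenerate"))
  }
  occupancy(params)  # validates k_on + k_off > 0
  p <- pmf_vector(params, label_time)
  n_max <- findInterval(1 - tail_eps, cumsum(p)) + 1L
  n_max <- min(n_max, length(p))
  new_pulse_pmf(p[seq_len(n_max)], params, label_time, tail_eps,
                "characteristics")
}

# Gauss-Legendre nodes/weights on [-1, 1], cached per order
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    # Golub-Welsch: eigen-decomposition of the Jacobi matrix
    k <- seq_len(n - 1)
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    .gl_cache[[key]] <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  }
  .gl_cache[[key]]
}

# stationary PMF by quadrature over the Beta occupancy density; fast route
# for steady-state likelihood evaluation (the series-based
# steady_state_pmf() is the reference implementation)
steady_pmf_quad <- function(params, n_min = 0L, n_nodes = 200L) {
  al <- params$k_on / params$k_d
  be <- params$k_off / params$k_d
  lam <- params$k_syn / params$k_d
  if (params$k_off == 0) {
    n_max <- max(n_min, stats::qpois(1 - 1e-12, lam) + 1)
    return(stats::dpois(0:n_max, lam))
  }
  lo <- stats::qbeta(1e-14, al, be)
  hi <- stats::qbeta(1 - 1e-14, al, be)
  gl <- gauss_legendre(n_nodes)
  u <- (hi + lo) / 2 + (hi - lo) / 2 * gl$x
  w <- (hi - lo) / 2 * gl$w * stats::dbeta(u, al, be)
  mu <- lam * al / (al + be)
  sd <- sqrt(mu + lam^2 * al * be / ((al + be)^2 * (al + be + 1)))
  n_max <- max(n_min, ceiling(mu + 12 * sd + 30))
  n <- 0:n_max
  dm <- matrix(stats::dpois(rep(n, length(u)), rep(lam * u, each = length(n))),
               nrow = length(n))
  p <- as.vector(dm %*% w)
  p[p < 0] <- 0
  p
}

# log M(a; b; x) for x >= 0, 0 < a <= b, by positive-term series in log space
log_kummer_m_pos <- function(a, b, x) {
  if (x == 0) return(0)
  k_max <- ceiling(x + 12 * sqrt(x) + 120)
  k <- seq_len(k_max)
  log_terms <- cumsum(log(a + k - 1) - log(b + k - 1) - log(k) + log(x))
  mx <- max(0, log_terms)
  mx + log(sum(exp(c(0, log_terms) - mx)))
}

#' Steady-state (Poisson-beta) PMF of telegraph RNA counts
#'
#' The long-time limit of the labelled-count distribution: a Poisson-beta
#' distribution with shape parameters `k_on / k_d` and `k_off / k_d` and
#' scale `k_syn / k_d`. Entries are evaluated through the confluent
#' hypergeometric representation, computed as a positive-term series in log
#' space so that no cancellation occurs.
#'
#' @inheritParams transient_pmf
#' @return A `pulse_pmf` object (with `label_time = Inf`).
#' @export
steady_state_pmf <- function(params, tail_eps = 1e-10) {
  params <- as_kinetic_params(params)
  if (params$k_d <= 0) stop("steady state requires k_d > 0")
  if (tail_eps <= 0 || tail_eps > 1e-4) stop("tail_eps must be in (0, 1e-4]")
  if (params$k_syn == 0 || params$k_on == 0) {
    return(new_pulse_pmf(1, params, Inf, tail_eps, "degenerate"))
  }
  al <- params$k_on / params$k_d
  be <- params$k_off / params$k_d
  lam <- params$k_syn / params$k_d
  if (params$k_off == 0) {
    n_max <- stats::qpois(1 - tail_eps, lam) + 1L
    return(new_pulse_pmf(stats::dpois(0:n_max, lam), params, Inf, tail_eps,
                         "poisson"))
  }
  mu <- lam * al / (al + be)
  v <- mu + lam^2 * al * be / ((al + be)^2 * (al + be + 1))
  n_hi <- ceiling(mu + 12 * sqrt(v) + 50)
  repeat {
    n <- 0:n_hi
    logp <- lgamma(al + n) - lgamma(al) + lgamma(al + be) -
      lgamma(al + be + n) + n * log(lam) - lgamma(n + 1) - lam +
      vapply(n, function(k) log_kummer_m_pos(be, al + be + k, lam), 0)
    p <- exp(logp)
    cp <- cumsum(p)
    if (1 - cp[length(cp)] < tail_eps) {
      n_max <- findInterval(1 - tail_eps, cp) + 1L
      return(new_pulse_pmf(p[seq_len(min(n_max, length(p)))], params, Inf,
                           tail_eps, "poisson-beta"))
    }
    n_hi <- n_hi * 2L
  }
}

#' Chemical-master-equation oracle PMF
#'
#' Independent verification oracle for [transient_pmf()]: integrates the
#' chemical master equation over the promoter-state x labelled-count state
#' space truncated at `n_max` (finite state projection), using a stiff ODE
#' solver. Intended for testing; it shares no code path with the
#' generating-function evaluation.
#'
#' @inheritParams transient_pmf
#' @param n_max Count-space truncation; mass at the boundary must stay
#'   below 1e-10 or an error is raised.
#' @return A `pulse_pmf` object.
#' @export
cme_oracle_pmf <- function(params, label_time, n_max) {
  params <- as_kinetic_params(params)
  stopifnot(label_time >= 0, n_max >= 1)
  occ <- occupancy(params)
  n_states <- n_max + 1L
  n <- 0:n_max
  k_on <- params$k_on; k_off <- params$k_off
  k_syn <- params$k_syn; k_d <- params$k_d
  # indices: off-block 1..n_states, on-block n_states+1..2*n_states
  i_off <- seq_len(n_states); i_on <- n_states + i_off
  ii <- c(i_off, i_on,                         # switching out/in
          i_on, i_off,
          i_on[-n_states],                     # synthesis leaves (on, n)
          i_on[-1],                            # ... and enters (on, n+1)
          i_off, i_on,                         # degradation leaves (., n)
          i_off[-n_states], i_on[-n_states])   # ... enters (., n-1)
  jj <- c(i_off, i_off,
          i_on, i_on,
          i_on[-n_states],
          i_on[-n_states],
          i_off, i_on,
          i_off[-1], i_on[-1])
  xx <- c(rep(-k_on, n_states), rep(k_on, n_states),
          rep(-k_off, n_states), rep(k_off, n_states),
          rep(-k_syn, n_states - 1L),
          rep(k_syn, n_states - 1L),
          -k_d * n, -k_d * n,
          k_d * n[-1], k_d * n[-1])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(2L * n_states, 2L * n_states))
  y0 <- numeric(2L * n_states)
  y0[1] <- 1 - occ
  y0[n_states + 1L] <- occ
  if (label_time == 0) {
    p <- y0[i_off] + y0[i_on]
  } else {
    rhs <- function(s, y, parms) list(as.numeric(A %*% y))
    sol <- deSolve::ode(y = y0, times = c(0, label_time), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-15, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("CME oracle integration failed to meet tolerance")
    }
    y <- unname(sol[nrow(sol), -1])
    p <- y[i_off] + y[i_on]
  }
  if (p[n_states] > 1e-10) {
    stop("CME oracle truncation boundary mass exceeds 1e-10; increase n_max")
  }
  p[p < 0 & p > -1e-12] <- 0
  new_pulse_pmf(p, params, label_time, 1e-10, "cme-oracle")
}

#' Log-likelihood of new-RNA counts under the telegraph model
#'
#' Sum over cells of `log P(n_i | params, label_time)` with `P` the transient
#' labelled-count PMF; the PMF support is extended to cover the largest
#' observed count.
#'
#' @param counts Non-negative integer vector of per-cell new-RNA counts.
#' @inheritParams transient_pmf
#' @return The log-likelihood. If any count has zero probability at working
#'   precision, `-Inf` is returned with attribute `zero_prob = TRUE`.
#' @export
log_likelihood <- function(counts, params, label_time) {
  params <- as_kinetic_params(params)
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  counts <- as.integer(counts)
  if (params$k_syn == 0 || label_time == 0 || params$k_on == 0) {
    if (all(counts == 0)) return(0)
    return(structure(-Inf, zero_prob = TRUE))
  }
  p <- pmf_vector(params, label_time, n_min = max(counts))
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  probs <- p[seq_along(tab)]
  if (any(probs[tab > 0] <= 0)) {
    return(structure(-Inf, zero_prob = TRUE))
  }
  sum(tab[tab > 0] * log(probs[tab > 0]))
}

#' Export a PMF as a two-column TSV
#'
#' @param pmf A `pulse_pmf` object.
#' @param path Output path.
#' @param header Logical; prepend the standard provenance comment header.
#' @return The path, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path, header = TRUE) {
  stopifnot(inherits(pmf, "pulse_pmf"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(output_header(list(label_time = pmf$label_time,
                                  tail_eps = pmf$tail_eps,
                                  method = pmf$method)), con)
  }
  writeLines("count\tprobability", con)
  writeLines(sprintf("%d\t%.17g", seq_along(pmf$probs) - 1L, pmf$probs), con)
  invisible(path)
}
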