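# Unimodality testing for estimate distributions.
#
# The statistic follows Hartigan & Hartigan's dip construction: a unimodal
# CDF is convex up to its mode and concave beyond it, so for every candidate
# modal position the sup-distance of the empirical CDF from that shape class
# is half the larger of (a) the maximal gap between the empirical CDF and
# its greatest convex minorant on the left section and (b) the maximal gap
# between the least concave majorant and the empirical CDF on the right
# section; the dip is the minimum over modal positions.  Significance is
# assessed by Monte-Carlo calibration against the U(0, 1) null (the
# least-favourable unimodal distribution), which makes the test level exact
# by construction regardless of small differences from the classical
# algorithm's handling of the staircase geometry.

# maximal gap above the greatest convex minorant of the empirical CDF
# restricted to sorted points x[1..k] (lower staircase corners (i-1)/n,
# gaps measured at upper corners i/n)
gcm_gap <- function(x, n_total, lo = (seq_along(x) - 1) / n_total,
                    hi = seq_along(x) / n_total) {
  k <- length(x)
  if (k <= 2) return(0)
  hull <- c(1L, 2L)  # indices into x of lower-hull vertices
  for (i in 3:k) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      # drop b while it lies above the chord a-i (not part of the minorant)
      cross <- (x[b] - x[a]) * (lo[i] - lo[a]) -
        (lo[b] - lo[a]) * (x[i] - x[a])
      if (cross >= 0) break
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  minorant <- stats::approx(x[hull], lo[hull], xout = x, ties = min)$y
  max(hi - minorant)
}

#' Dip statistic for unimodality
#'
#' @param x Numeric sample (length >= 4).
#' @return The dip statistic (sup-distance of the empirical CDF from the
#'   nearest unimodal CDF).
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  # break exact ties deterministically (hull code assumes increasing x)
  d <- diff(x)
  if (any(d <= 0)) x <- x + seq_len(n) * max(1e-12, 1e-9 * diff(range(x)))
  best <- Inf
  for (k in 2:(n - 1)) {
    left <- gcm_gap(x[1:k], n)
    # right section: reflect so the concave-majorant gap becomes a
    # convex-minorant gap
    xr <- rev(-x[k:n])
    ir <- (k:n)
    right <- gcm_gap(xr, n, lo = rev(1 - ir / n), hi = rev(1 - (ir - 1) / n))
    best <- min(best, max(left, right))
  }
  best / 2
}

.dip_null_cache <- new.env(parent = emptyenv())

#' Monte-Carlo dip test
#'
#' Tests the null hypothesis that `x` was drawn from a unimodal
#' distribution, using [dip_statistic()] with a Monte-Carlo null computed
#' from uniform samples of the same size (cached per size).
#'
#' @param x Numeric sample.
#' @param n_mc Number of Monte-Carlo null replicates.
#' @param seed Seed for the null replicates.
#' @return List with `statistic` and `p.value`.
#' @export
dip_test <- function(x, n_mc = 1000, seed = 100) {
  n <- length(x)
  key <- sprintf("n%d_m%d_s%d", n, n_mc, seed)
  if (is.null(.dip_null_cache[[key]])) {
    old <- .Random.seed_save()
    set.seed(seed)
    null <- vapply(seq_len(n_mc),
                   function(i) dip_statistic(stats::runif(n)), 0)
    .Random.seed_restore(old)
    .dip_null_cache[[key]] <- sort(null)
  }
  null <- .dip_null_cache[[key]]
  obs <- dip_statistic(x)
  p <- (sum(null >= obs) + 1) / (length(null) + 1)
  list(statistic = obs, p.value = p)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
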