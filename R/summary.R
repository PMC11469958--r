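#' Count summary statistics used for lookup initialisation
#'
#' The three per-gene summaries that index the lookup table: the fraction of
#' cells with any new RNA, the mean count among expressing cells, and the
#' coefficient of variation of counts among expressing cells. The CV uses
#' the population (divide-by-n) standard deviation so that table construction
#' and gene summaries follow one deterministic convention.
#'
#' @param counts Non-negative integer vector, length >= 1.
#' @return A list of class `summary_stats` with `frac_expressing`,
#'   `mean_expressing`, `cv_expressing`, `n_cells`, `n_expressing` and
#'   `defined` (FALSE when no cell expresses, in which case the latter two
#'   statistics are `NA`).
#' @examples
#' compute_summary_stats(c(0, 1, 3))
#' @export
compute_summary_stats <- function(counts) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  expressing <- counts > 0
  n_expr <- sum(expressing)
  if (n_expr == 0) {
    out <- list(frac_expressing = 0, mean_expressing = NA_real_,
                cv_expressing = NA_real_, n_cells = length(counts),
                n_expressing = 0L, defined = FALSE)
    return(structure(out, class = "summary_stats"))
  }
  x <- counts[expressing]
  m <- mean(x)
  sd_pop <- sqrt(mean((x - m)^2))
  structure(list(frac_expressing = n_expr / length(counts),
                 mean_expressing = m,
                 cv_expressing = sd_pop / m,
                 n_cells = length(counts),
                 n_expressing = as.integer(n_expr),
                 defined = TRUE),
            class = "summary_stats")
}

#' Degradation rate from the old-RNA fraction
#'
#' `k_d = -ln(fraction_old) / label_time`: the fraction of molecules still
#' unlabelled after the window determines the first-order decay rate.
#'
#' @param frac_old Fraction of molecules classified as old, in (0, 1\].
#' @param label_time Labelling time in hours (> 0).
#' @return Degradation rate per hour.
#' @examples
#' estimate_degradation(0.875, 2)
#' @export
estimate_degradation <- function(frac_old, label_time) {
  stopifnot(length(frac_old) == 1L, length(label_time) == 1L)
  if (!is.finite(frac_old) || frac_old <= 0 || frac_old > 1) {
    stop("frac_old must be in (0, 1]")
  }
  if (!is.finite(label_time) || label_time <= 0) {
    stop("label_time must be > 0")
  }
  -log(frac_old) / label_time
}

#' Geometric standard deviation between split-half estimates
#'
#' `exp(sqrt(mean((log(half1) - log(half2))^2) / 2))`, the technical-
#' variation summary for parameters estimated independently on two halves of
#' the cells.
#'
#' @param half1,half2 Positive vectors of equal length (per-gene estimates).
#' @return A scalar >= 1.
#' @examples
#' geometric_sd(c(1, 2, 4), exp(1) * c(1, 2, 4))
#' @export
geometric_sd <- function(half1, half2) {
  if (length(half1) != length(half2)) stop("halves must have equal length")
  if (length(half1) == 0) stop("empty input")
  if (any(!is.finite(half1)) || any(!is.finite(half2)) ||
      any(half1 <= 0) || any(half2 <= 0)) {
    stop("all entries must be positive and finite")
  }
  exp(sqrt(mean((log(half1) - log(half2))^2) / 2))
}
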