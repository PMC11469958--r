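#' Conversion model for new-RNA calling
#'
#' Two-component binomial mixture over per-molecule conversion counts:
#' convertible sites in new (labelled) molecules read converted with
#' probability `pc`, sites in old molecules with the error probability `pe`;
#' `pi_new` is the mixing fraction of new molecules. `pc/pe` is the
#' signal-to-noise ratio of the assay.
#'
#' @param pc Conversion probability per site in new molecules.
#' @param pe Apparent conversion (error) probability in old molecules.
#' @param pi_new Mixing fraction of new molecules.
#' @return An object of class `conversion_model`.
#' @export
conversion_model <- function(pc, pe, pi_new = NA_real_) {
  stopifnot(is.finite(pc), is.finite(pe), pc >= 0, pc <= 1, pe >= 0, pe <= 1)
  structure(list(pc = pc, pe = pe, pi_new = pi_new,
                 signal_to_noise = if (pe > 0) pc / pe else Inf),
            class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf("conversion model: pc=%.4g pe=%.4g pi_new=%.3g S/N=%.3g\n",
              x$pc, x$pe, x$pi_new, x$signal_to_noise))
  invisible(x)
}

#' Merge reads sharing a UMI into one molecule consensus
#'
#' Combines base calls of reads from the same (error-corrected) UMI group.
#' Per position, each read contributes a likelihood over the four bases
#' (`1 - 10^(-Q/10)` for its called base, the remainder split equally over
#' the other three; a sequencer `N` contributes uniformly); likelihoods are
#' multiplied across reads and normalised. The most likely base is called
#' when its normalised probability exceeds 0.3 (ties give `N`), and the
#' merged Phred score is `-10 log10(1 - p_max)`, capped at 93.
#'
#' @param reads Data.frame with columns `read` (identifier), `pos`
#'   (position), `base` (A/C/G/T/N) and `qual` (numeric Phred score).
#' @return Data.frame with one row per position: `pos`, `base`, `qual`,
#'   `p_max`.
#' @examples
#' merge_read_group(data.frame(read = 1:2, pos = 10, base = "T", qual = 30))
#' @export
merge_read_group <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0) stop("empty read group")
  stopifnot(all(c("read", "pos", "base", "qual") %in% names(reads)))
  bases <- c("A", "C", "G", "T")
  out <- lapply(split(reads, reads$pos), function(at_pos) {
    loglik <- numeric(4)
    for (r in seq_len(nrow(at_pos))) {
      b <- toupper(at_pos$base[r])
      if (b == "N") {
        lik <- rep(0.25, 4)
      } else {
        p_ok <- 1 - 10^(-at_pos$qual[r] / 10)
        lik <- rep((1 - p_ok) / 3, 4)
        lik[match(b, bases)] <- p_ok
      }
      loglik <- loglik + log(lik)
    }
    prob <- exp(loglik - max(loglik))
    prob <- prob / sum(prob)
    p_max <- max(prob)
    top <- which(prob > p_max - 1e-12)
    call <- if (length(top) > 1 || p_max <= 0.3) "N" else bases[top]
    qual <- min(93, -10 * log10(max(1 - p_max, 1e-12)))
    data.frame(pos = at_pos$pos[1], base = call, qual = qual, p_max = p_max)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pos), , drop = FALSE]
}

#' Mask positions with recurrent mismatches
#'
#' Flags genomic positions whose mismatch recurrence across molecules is
#' incompatible with the gene's background mismatch rate: a one-sided
#' upper-tail binomial test per position with `p` equal to the median
#' per-position mismatch fraction, Bonferroni-corrected over the positions
#' tested. Such positions are typically unfiltered genetic polymorphism or
#' alignment artifacts and are excluded from conversion counting.
#'
#' @param position_stats Data.frame with columns `pos`, `n_molecules`
#'   (molecules covering the position) and `n_mismatch` (molecules with the
#'   mismatch).
#' @param alpha Family-wise significance level.
#' @return The input with columns `p_value` and `masked` added; masked
#'   positions are also available as `attr(, "masked_positions")`.
#' @export
mask_artifact_positions <- function(position_stats, alpha = 0.05) {
  stopifnot(nrow(position_stats) >= 1,
            all(c("pos", "n_molecules", "n_mismatch") %in%
                  names(position_stats)))
  p_bg <- stats::median(position_stats$n_mismatch /
                          position_stats$n_molecules)
  m <- nrow(position_stats)
  p_val <- stats::pbinom(position_stats$n_mismatch - 1,
                         position_stats$n_molecules, p_bg,
                         lower.tail = FALSE)
  position_stats$p_value <- p_val
  position_stats$masked <- p_val < alpha / m
  attr(position_stats, "masked_positions") <-
    position_stats$pos[position_stats$masked]
  position_stats
}

#' Estimate the conversion error rate
#'
#' The error probability `pe` is the mean of the C>T and G>A mismatch rates,
#' the strand-complementary counterparts of the 4sU-induced T>C / A>G
#' conversions: they share the sequencing/library error process but carry no
#' labelling signal.
#'
#' @param molecules Data.frame with per-molecule columns `n_c_sites`,
#'   `n_c_to_t`, `n_g_sites`, `n_g_to_a`.
#' @return `pe` (scalar); zero is returned with attribute
#'   `degenerate = TRUE` since a zero error rate makes the downstream
#'   likelihood-ratio test degenerate.
#' @export
estimate_error_rate <- function(molecules) {
  need <- c("n_c_sites", "n_c_to_t", "n_g_sites", "n_g_to_a")
  stopifnot(all(need %in% names(molecules)))
  c_sites <- sum(molecules$n_c_sites)
  g_sites <- sum(molecules$n_g_sites)
  if (c_sites == 0 || g_sites == 0) {
    stop("no covered C or G reference sites; cannot estimate error rate")
  }
  pe <- (sum(molecules$n_c_to_t) / c_sites +
           sum(molecules$n_g_to_a) / g_sites) / 2
  if (pe == 0) attr(pe, "degenerate") <- TRUE
  pe
}

#' EM estimation of the conversion probability
#'
#' Fits the two-component binomial mixture to per-molecule
#' (convertible, converted) site counts with the error probability `pe`
#' held fixed, estimating the conversion probability `pc` and the new-RNA
#' mixing fraction `pi_new` by expectation-maximisation. The observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param molecules Data.frame with columns `n_convertible`, `n_converted`.
#' @param pe Fixed error probability (from [estimate_error_rate()]).
#' @param tol Convergence threshold on the parameter change.
#' @param max_iter Iteration cap.
#' @return A `conversion_model` with extra fields `loglik` (trace),
#'   `converged`, `flag` (`NA` or a degeneracy description).
#' @export
em_conversion_rate <- function(molecules, pe, tol = 1e-8, max_iter = 500) {
  stopifnot(all(c("n_convertible", "n_converted") %in% names(molecules)))
  n <- molecules$n_convertible
  k <- molecules$n_converted
  if (length(n) < 10) stop("need at least 10 molecules")
  if (any(k > n) || any(n < 0)) stop("invalid site counts")
  rate <- sum(k) / max(1, sum(n))
  pc <- clamp(3 * rate, max(5 * pe, 1e-4), 0.5)
  pi_new <- 0.2
  ll_trace <- numeric(0)
  flag <- NA_character_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    la <- stats::dbinom(k, n, pc, log = TRUE) + log(pi_new)
    lb <- stats::dbinom(k, n, pe, log = TRUE) + log1p(-pi_new)
    mx <- pmax(la, lb)
    ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
    ll_trace <- c(ll_trace, ll)
    r <- 1 / (1 + exp(lb - la))
    pc_new <- sum(r * k) / max(1e-300, sum(r * n))
    pi_new2 <- mean(r)
    delta <- max(abs(pc_new - pc), abs(pi_new2 - pi_new))
    pc <- pc_new
    pi_new <- clamp(pi_new2, 1e-12, 1 - 1e-12)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (pc <= 2 * pe) {
    flag <- "unidentifiable: pc did not separate from pe"
  }
  if (sum(k) == 0) flag <- "degenerate: no conversions observed"
  model <- conversion_model(pc, pe, pi_new)
  model$loglik <- ll_trace
  model$converged <- converged
  model$flag <- flag
  model
}

# smallest conversion count whose old-molecule (error) tail probability is
# below alpha: the LRT rejection region, which by monotonicity of the
# binomial likelihood ratio in k (for pc > pe) is an upper tail
lrt_critical_k <- function(n_convertible, pe, alpha) {
  if (n_convertible == 0) return(NA_integer_)
  k <- 0:n_convertible
  tail <- stats::pbinom(k - 1, n_convertible, pe, lower.tail = FALSE)
  idx <- which(tail <= alpha)
  if (length(idx) == 0) return(n_convertible + 1L)
  k[idx[1]]
}

#' Classify a molecule as new or old
#'
#' One-sided binomial likelihood-ratio test: the null hypothesis is that
#' conversions arise from the error process (`p = pe`, old molecule), the
#' alternative that they arise from 4sU incorporation (`p = pc`, new
#' molecule). The molecule is called new when the null is rejected at
#' `alpha`; the call is monotone in the conversion count.
#'
#' @param n_convertible Covered convertible (transcript-strand T) sites.
#' @param n_converted Observed conversions.
#' @param model A `conversion_model`.
#' @param alpha Significance level.
#' @return `"new"`, `"old"`, or `"uncalled"` (no convertible sites);
#'   vectorised over molecules.
#' @export
classify_molecule <- function(n_convertible, n_converted, model,
                              alpha = 0.05) {
  stopifnot(inherits(model, "conversion_model"))
  stopifnot(length(n_convertible) == length(n_converted))
  mapply(function(n, k) {
    if (n == 0) return("uncalled")
    if (k > n) stop("n_converted exceeds n_convertible")
    kc <- lrt_critical_k(n, model$pe, alpha)
    if (k >= kc) "new" else "old"
  }, n_convertible, n_converted)
}

#' Power to call a new molecule
#'
#' Probability that a truly new molecule (conversions binomial with
#' probability `pc`) is called new by [classify_molecule()], computed by
#' exact enumeration of the rejection region.
#'
#' @inheritParams classify_molecule
#' @return Power in \[0, 1\]; vectorised over `n_convertible`.
#' @export
detection_power <- function(n_convertible, model, alpha = 0.05) {
  stopifnot(inherits(model, "conversion_model"))
  vapply(n_convertible, function(n) {
    if (n == 0) return(0)
    kc <- lrt_critical_k(n, model$pe, alpha)
    if (kc > n) return(0)
    stats::pbinom(kc - 1, n, model$pc, lower.tail = FALSE)
  }, 0)
}

#' Genotype a molecule from strain-discriminating variants
#'
#' Exclusive-evidence rule: a molecule is assigned maternal or paternal only
#' when every observed discriminating variant supports that single parent;
#' mixed or absent evidence leaves it unassigned.
#'
#' @param n_maternal,n_paternal Counts of observed maternal- and
#'   paternal-supporting variant bases (vectorised).
#' @return `"maternal"`, `"paternal"` or `"unassigned"`.
#' @export
genotype_molecule <- function(n_maternal, n_paternal) {
  stopifnot(length(n_maternal) == length(n_paternal))
  ifelse(n_maternal > 0 & n_paternal == 0, "maternal",
         ifelse(n_paternal > 0 & n_maternal == 0, "paternal", "unassigned"))
}

#' Sample quality filter on molecule totals
#'
#' Keeps cells with strictly more reconstructed molecules than the
#' threshold. Presets: 4,000 molecules for primary fibroblasts and 2,700
#' for K562 cells (the valley of the bimodal per-cell molecule-count
#' distribution in each dataset).
#'
#' @param totals Named vector of per-cell molecule totals.
#' @param threshold Count threshold, or a preset name
#'   (`"fibroblast"`, `"k562"`).
#' @return Character vector (or indices when `totals` is unnamed) of kept
#'   cells.
#' @export
sample_qc_filter <- function(totals, threshold = "fibroblast") {
  if (is.character(threshold)) {
    threshold <- switch(match.arg(threshold, c("fibroblast", "k562")),
                        fibroblast = 4000, k562 = 2700)
  }
  stopifnot(threshold >= 0)
  keep <- which(totals > threshold)
  if (!is.null(names(totals))) names(totals)[keep] else keep
}

#' Read-level temporal and allelic calls
#'
#' Applies the molecule-level conversion model at read resolution: each read
#' (pair) is assigned an allele by the exclusive-variant rule (reads without
#' transcribed genetic variation are removed) and a temporal state by the
#' same likelihood-ratio test on its convertible/converted site counts.
#'
#' @param reads Data.frame with columns `cell`, `gene`, `n_maternal`,
#'   `n_paternal`, `n_convertible`, `n_converted`.
#' @param model A fitted `conversion_model` (molecule-level `pc`, `pe`).
#' @param alpha Significance level for the temporal call.
#' @return The subset of reads carrying variants, with `allele` and
#'   `temporal_call` columns added.
#' @export
call_reads <- function(reads, model, alpha = 0.05) {
  need <- c("cell", "gene", "n_maternal", "n_paternal", "n_convertible",
            "n_converted")
  stopifnot(all(need %in% names(reads)))
  if (nrow(reads) == 0) {
    reads$allele <- character(0)
    reads$temporal_call <- character(0)
    return(reads)
  }
  keep <- reads$n_maternal + reads$n_paternal > 0
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$allele <- character(0)
    out$temporal_call <- character(0)
    return(out)
  }
  out$allele <- genotype_molecule(out$n_maternal, out$n_paternal)
  out$temporal_call <- classify_molecule(out$n_convertible, out$n_converted,
                                         model, alpha)
  rownames(out) <- NULL
  out
}
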