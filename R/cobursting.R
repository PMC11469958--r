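#' Allele-resolved new-RNA count matrix
#'
#' Container for gene-by-cell new-RNA counts split by parental allele, plus
#' gene coordinates for genomic-distance binning. Cells without
#' allele-assigned new RNA for a gene carry zeros (absence of new RNA is
#' signal for burst detection, not missing data).
#'
#' @param maternal,paternal Gene-by-cell integer matrices with identical
#'   dimnames.
#' @param coords Data.frame with columns `gene`, `chrom`, `start` (one row
#'   per gene, matching the matrix rows).
#' @return An object of class `allelic_counts`.
#' @export
allelic_counts <- function(maternal, paternal, coords) {
  stopifnot(is.matrix(maternal), is.matrix(paternal),
            all(dim(maternal) == dim(paternal)),
            all(c("gene", "chrom", "start") %in% names(coords)),
            nrow(coords) == nrow(maternal))
  if (any(maternal < 0) || any(paternal < 0)) {
    stop("counts must be non-negative")
  }
  if (any(coords$start < 0)) stop("coordinates must be non-negative")
  rownames(maternal) <- rownames(paternal) <- coords$gene
  structure(list(maternal = maternal, paternal = paternal,
                 coords = coords), class = "allelic_counts")
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat(sprintf("allelic new-RNA counts: %d genes x %d cells x 2 alleles\n",
              nrow(x$maternal), ncol(x$maternal)))
  invisible(x)
}

#' @export
dim.allelic_counts <- function(x) dim(x$maternal)

default_distance_bins <- function() c(0.1, 0.5, 1.5, 2.5, 3.5) * 1e6

spearman <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Pairwise cis/trans correlations of allelic new-RNA counts
#'
#' For every same-chromosome gene pair within `max_distance`, computes
#' Spearman correlations of the total (allele-agnostic) new-RNA counts, of
#' the same-allele pairings (maternal-maternal and paternal-paternal,
#' averaged; the cis correlation) and of the cross-allele pairings
#' (maternal-paternal both ways, averaged; the trans control), and assigns
#' each pair to a genomic-distance bin. Gene pairs where either count
#' vector has zero variance are reported with `NA` correlations and counted
#' in `attr(, "n_undefined")`.
#'
#' @param ac An [allelic_counts()] object.
#' @param max_distance Maximum gene-start separation in bases.
#' @param bins Upper edges (bases) of the distance bins; the defaults follow
#'   the <0.1 / <0.5 / <1.5 / <2.5 / <3.5 megabase convention.
#' @return A data.frame of class `gene_pair_results`: one row per pair with
#'   `corr_total`, `corr_cis`, `corr_trans`, `cis_minus_trans`, `distance`,
#'   `bin`.
#' @export
pairwise_correlations <- function(ac, max_distance = 3.5e6,
                                  bins = default_distance_bins()) {
  stopifnot(inherits(ac, "allelic_counts"))
  co <- ac$coords
  rows <- list()
  n_undefined <- 0L
  for (a in seq_len(nrow(co) - 1L)) {
    for (b in seq((a + 1L), nrow(co))) {
      if (co$chrom[a] != co$chrom[b]) next
      d <- abs(co$start[a] - co$start[b])
      if (d > max_distance) next
      am <- ac$maternal[a, ]; ap <- ac$paternal[a, ]
      bm <- ac$maternal[b, ]; bp <- ac$paternal[b, ]
      r_tot <- spearman(am + ap, bm + bp)
      r_mm <- spearman(am, bm); r_pp <- spearman(ap, bp)
      r_mp <- spearman(am, bp); r_pm <- spearman(ap, bm)
      cis <- mean(c(r_mm, r_pp)); trans <- mean(c(r_mp, r_pm))
      if (any(is.na(c(r_tot, cis, trans)))) n_undefined <- n_undefined + 1L
      bin_idx <- findInterval(d, bins, left.open = TRUE) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = co$gene[a], gene_b = co$gene[b], distance = d,
        bin = if (bin_idx <= length(bins))
          sprintf("<%g", bins[bin_idx] / 1e6) else NA_character_,
        corr_total = r_tot, corr_cis = cis, corr_trans = trans,
        cis_minus_trans = cis - trans, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               distance = numeric(0), bin = character(0),
               corr_total = numeric(0), corr_cis = numeric(0),
               corr_trans = numeric(0), cis_minus_trans = numeric(0))
  class(out) <- c("gene_pair_results", "data.frame")
  attr(out, "n_undefined") <- n_undefined
  attr(out, "bins") <- bins
  out
}

#' Cis-minus-trans statistic with per-bin summaries
#'
#' The per-pair difference between the same-allele and cross-allele
#' correlations isolates allele-level co-bursting from cell-level
#' confounders (which inflate cis and trans alike). Relabelling the alleles
#' of one gene in a pair exchanges cis and trans and negates the statistic.
#'
#' @param pairs A `gene_pair_results` data.frame.
#' @return List with `pairs` (rows with defined statistic) and `by_bin`
#'   (per-bin n, median and quartiles of cis minus trans).
#' @export
cis_minus_trans <- function(pairs) {
  ok <- pairs[!is.na(pairs$cis_minus_trans), , drop = FALSE]
  by_bin <- do.call(rbind, lapply(split(ok, ok$bin), function(s) {
    q <- stats::quantile(s$cis_minus_trans, c(0.25, 0.5, 0.75),
                         names = FALSE)
    data.frame(bin = s$bin[1], n_pairs = nrow(s), q25 = q[1],
               median = q[2], q75 = q[3], stringsAsFactors = FALSE)
  }))
  if (!is.null(by_bin)) {
    by_bin <- by_bin[order(match(by_bin$bin,
                                 sprintf("<%g",
                                         attr(pairs, "bins") / 1e6))), ]
    rownames(by_bin) <- NULL
  }
  list(pairs = ok, by_bin = by_bin)
}

# 2x2 allele-of-expression table over cells expressing both genes
# mono-allelically
allele_table_2x2 <- function(ac, gene_a, gene_b) {
  a <- match(gene_a, ac$coords$gene)
  b <- match(gene_b, ac$coords$gene)
  stopifnot(!is.na(a), !is.na(b))
  call_allele <- function(m, p) {
    ifelse(m > 0 & p == 0, "M", ifelse(p > 0 & m == 0, "P", NA))
  }
  al_a <- call_allele(ac$maternal[a, ], ac$paternal[a, ])
  al_b <- call_allele(ac$maternal[b, ], ac$paternal[b, ])
  keep <- !is.na(al_a) & !is.na(al_b)
  table(factor(al_a[keep], c("M", "P")), factor(al_b[keep], c("M", "P")))
}

#' Contingency tests for allele-coupled expression of a gene pair
#'
#' Builds the 2x2 table of expressed allele (maternal/paternal) of gene A
#' against gene B over cells expressing both genes mono-allelically, and
#' applies the chi-square and Fisher exact tests (both two-sided).
#'
#' @param ac An [allelic_counts()] object.
#' @param gene_a,gene_b Gene identifiers.
#' @return List with `table`, `chisq_p`, `fisher_p`, `flag` (`NA` or
#'   `"zero margin"` when a margin is empty, in which case the p-values are
#'   `NA`).
#' @export
contingency_tests <- function(ac, gene_a, gene_b) {
  tab <- allele_table_2x2(ac, gene_a, gene_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, chisq_p = NA_real_, fisher_p = NA_real_,
                flag = "zero margin"))
  }
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fis <- stats::fisher.test(tab)
  list(table = tab, chisq_p = chi$p.value, fisher_p = fis$p.value,
       flag = NA_character_)
}

# the pair test used for power analysis: Spearman correlation over the
# pooled same-allele pairings (M-M and P-P observations concatenated),
# two-sided; calibrated under independence, sensitive to same-allele
# coordination
cis_pair_test <- function(ac, a, b) {
  x <- c(ac$maternal[a, ], ac$paternal[a, ])
  y <- c(ac$maternal[b, ], ac$paternal[b, ])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                   exact = FALSE)$p.value)
}

#' Power to detect implanted co-bursting
#'
#' Estimates detection power by synthetically implanting coordinated
#' same-allele new-RNA counts into an increasing fraction of cells of an
#' independence-simulated baseline, and measuring the rejection rate of the
#' pair test across replicates. Each replicate draws a fresh eligible gene
#' pair from the baseline (all pairs are independent by construction), so
#' at fraction 0 the rejection rate estimates the test's level.
#'
#' @param ac Baseline [allelic_counts()] simulated under independence.
#' @param implant_fractions Fractions of cells receiving coordinated
#'   counts.
#' @param n_reps Replicates per fraction.
#' @param alpha Test level.
#' @param implant_lambda Mean of the (1 + Poisson) coordinated count added
#'   to both genes on one randomly chosen allele per implanted cell; the
#'   scale of one typical burst's worth of new RNA.
#' @param mean_range Eligibility window on the per-allele mean count of the
#'   genes drawn for each replicate (well-detected but not saturating).
#' @param seed Integer seed.
#' @return Data.frame with `fraction`, `power`, `n_reps`.
#' @export
implantation_power <- function(ac,
                               implant_fractions = c(0, 0.01, 0.02, 0.05,
                                                     0.1, 0.2),
                               n_reps = 50, alpha = 0.05,
                               implant_lambda = 2,
                               mean_range = c(0.2, 5), seed = 1) {
  stopifnot(inherits(ac, "allelic_counts"))
  mean_allele <- (rowMeans(ac$maternal) + rowMeans(ac$paternal)) / 2
  eligible <- which(mean_allele >= mean_range[1] &
                      mean_allele <= mean_range[2])
  if (length(eligible) < 2) stop("fewer than two eligible genes")
  set.seed(seed)
  n_cells <- ncol(ac$maternal)
  rows <- lapply(implant_fractions, function(f) {
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      pair <- sample(eligible, 2)
      a <- pair[1]
      b <- pair[2]
      aci <- ac
      n_imp <- round(f * n_cells)
      if (n_imp > 0) {
        cells <- sample.int(n_cells, n_imp)
        allele_m <- stats::runif(n_imp) < 0.5
        add <- 1L + stats::rpois(n_imp, implant_lambda)
        add2 <- 1L + stats::rpois(n_imp, implant_lambda)
        im <- cells[allele_m]; ip <- cells[!allele_m]
        aci$maternal[a, im] <- aci$maternal[a, im] + add[allele_m]
        aci$maternal[b, im] <- aci$maternal[b, im] + add2[allele_m]
        aci$paternal[a, ip] <- aci$paternal[a, ip] + add[!allele_m]
        aci$paternal[b, ip] <- aci$paternal[b, ip] + add2[!allele_m]
      }
      p <- cis_pair_test(aci, a, b)
      rej[r] <- !is.na(p) && p < alpha
    }
    data.frame(fraction = f, power = mean(rej), n_reps = n_reps)
  })
  do.call(rbind, rows)
}

#' Export gene-pair co-bursting results as TSV
#'
#' @param pairs A `gene_pair_results` data.frame.
#' @param path Output path.
#' @param seed Seed echoed into the header.
#' @return The path, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(list(kind = "gene_pair_results"), seed = seed),
             con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
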