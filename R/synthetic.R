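#' Generate a synthetic gene panel
#'
#' Draws per-gene telegraph kinetics log-uniformly within realistic
#' fibroblast-like ranges: burst frequencies (`k_on`) from about one per day
#' to one per hour, synthesis rates from 3 to 200 molecules per hour, and
#' off-rates large relative to on-rates so genes are bursty. Genes are
#' placed along one chromosome with log-uniform spacings so that all
#' genomic-distance bins up to a few megabases are populated. Optionally,
#' consecutive genes are paired as co-bursting partners that share one
#' promoter on/off trajectory per allele (which requires the pair to share
#' `k_on` and `k_off`).
#'
#' @param n_genes Number of genes (>= 0).
#' @param kon_range,koff_range,ksyn_range Log-uniform prior ranges
#'   (per hour).
#' @param coupled_fraction Fraction of genes belonging to a coupled pair
#'   (rounded down to whole pairs).
#' @param spacing_range Range of inter-gene start spacings in bases
#'   (log-uniform).
#' @param chrom Chromosome label.
#' @param seed Integer seed; the panel is deterministic given it.
#' @return A data.frame of class `gene_panel`: `gene`, `chrom`, `start`,
#'   `k_on`, `k_off`, `k_syn`, `partner` (NA or partner gene), `coupled`.
#' @export
generate_gene_panel <- function(n_genes,
                                kon_range = c(1 / 24, 1),
                                koff_range = c(5, 200),
                                ksyn_range = c(3, 200),
                                coupled_fraction = 0,
                                spacing_range = c(2e4, 2e6),
                                chrom = "chr1", seed = 1) {
  stopifnot(n_genes >= 0, coupled_fraction >= 0, coupled_fraction <= 1)
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] > 0 &&
    r[2] >= r[1]
  if (!rng_ok(kon_range) || !rng_ok(koff_range) || !rng_ok(ksyn_range) ||
      !rng_ok(spacing_range)) {
    stop("invalid prior range")
  }
  if (n_genes == 0) {
    return(structure(data.frame(gene = character(0), chrom = character(0),
                                start = numeric(0), k_on = numeric(0),
                                k_off = numeric(0), k_syn = numeric(0),
                                partner = character(0), coupled = logical(0)),
                     class = c("gene_panel", "data.frame"), seed = seed))
  }
  set.seed(seed)
  draw <- function(r, n) exp(stats::runif(n, log(r[1]), log(r[2])))
  k_on <- draw(kon_range, n_genes)
  k_off <- draw(koff_range, n_genes)
  k_syn <- draw(ksyn_range, n_genes)
  start <- cumsum(draw(spacing_range, n_genes))
  gene <- sprintf("g%04d", seq_len(n_genes))
  partner <- rep(NA_character_, n_genes)
  coupled <- rep(FALSE, n_genes)
  n_pairs <- floor(coupled_fraction * n_genes / 2)
  if (n_pairs > 0) {
    for (p in seq_len(n_pairs)) {
      a <- 2L * p - 1L
      b <- 2L * p
      partner[a] <- gene[b]
      partner[b] <- gene[a]
      coupled[c(a, b)] <- TRUE
      # a shared promoter trajectory requires shared switching rates
      k_on[b] <- k_on[a]
      k_off[b] <- k_off[a]
    }
  }
  structure(data.frame(gene = gene, chrom = chrom, start = start,
                       k_on = k_on, k_off = k_off, k_syn = k_syn,
                       partner = partner, coupled = coupled,
                       stringsAsFactors = FALSE),
            class = c("gene_panel", "data.frame"), seed = seed)
}

#' Simulate an allelic new-RNA count matrix from a gene panel
#'
#' Runs the labelled-RNA Gillespie simulation per gene and allele: the two
#' alleles of every gene are independent, and coupled gene pairs share one
#' promoter trajectory per allele (same-allele co-bursting by
#' construction).
#'
#' @param panel A [generate_gene_panel()] data.frame.
#' @param n_cells Number of cells.
#' @param label_time Labelling window in hours.
#' @param k_d Degradation rate per hour.
#' @param seed Integer seed.
#' @return An [allelic_counts()] object.
#' @export
generate_count_matrix <- function(panel, n_cells, label_time = 2,
                                  k_d = 0.065, seed = 1) {
  stopifnot(inherits(panel, "gene_panel"), n_cells >= 1)
  set.seed(seed)
  n_genes <- nrow(panel)
  mat_m <- matrix(0L, n_genes, n_cells)
  mat_p <- matrix(0L, n_genes, n_cells)
  done <- rep(FALSE, n_genes)
  for (g in seq_len(n_genes)) {
    if (done[g]) next
    if (panel$coupled[g]) {
      h <- match(panel$partner[g], panel$gene)
      for (allele in c("m", "p")) {
        sim <- .sim_labelled_pair(panel$k_on[g], panel$k_off[g],
                                  panel$k_syn[g], panel$k_syn[h], k_d,
                                  label_time, as.integer(n_cells))
        if (allele == "m") {
          mat_m[g, ] <- sim$counts_a
          mat_m[h, ] <- sim$counts_b
        } else {
          mat_p[g, ] <- sim$counts_a
          mat_p[h, ] <- sim$counts_b
        }
      }
      done[c(g, h)] <- TRUE
    } else {
      for (allele in c("m", "p")) {
        sim <- .sim_labelled(panel$k_on[g], panel$k_off[g], panel$k_syn[g],
                             k_d, label_time, as.integer(n_cells), FALSE)
        if (allele == "m") mat_m[g, ] <- sim$counts else
          mat_p[g, ] <- sim$counts
      }
      done[g] <- TRUE
    }
  }
  colnames(mat_m) <- colnames(mat_p) <- sprintf("cell%04d",
                                                seq_len(n_cells))
  allelic_counts(mat_m, mat_p,
                 panel[, c("gene", "chrom", "start"), drop = FALSE])
}

#' Simulate a molecule table with conversions and allele evidence
#'
#' Expands an allelic count matrix into per-molecule records emulating the
#' conversion assay: each new molecule draws conversions
#' `Binomial(n_convertible, pc)` and each old molecule
#' `Binomial(n_convertible, pe)`; convertible-site counts follow a
#' discretised log-normal (median ~60 sites) standing in for the
#' molecule-length dependence of detection power; covered
#' strain-discriminating variants are Poisson with mean `snp_mean` and
#' support the molecule's true allele. Old-molecule background counts are
#' Poisson per gene and cell, scaled so that new molecules are a realistic
#' minority (about 1/8 of all molecules at the default
#' `old_total_factor = 7`).
#'
#' @param ac An [allelic_counts()] object of new-RNA counts.
#' @param model A [conversion_model()]; defaults to `pc = 0.04`,
#'   `pe = 0.002` (signal-to-noise 20, the fibroblast scale).
#' @param site_meanlog,site_sdlog Log-normal parameters of the
#'   convertible-site count per molecule.
#' @param snp_mean Mean covered discriminating variants per molecule.
#' @param old_total_factor Expected old molecules per new molecule.
#' @param seed Integer seed.
#' @return A data.frame with one row per molecule: `cell`, `gene`, `umi`,
#'   `allele_true`, `is_new_true`, `n_convertible`, `n_converted`,
#'   `n_maternal`, `n_paternal`.
#' @export
generate_molecule_table <- function(ac,
                                    model = conversion_model(0.04, 0.002),
                                    site_meanlog = log(60),
                                    site_sdlog = 0.6, snp_mean = 1,
                                    old_total_factor = 7, seed = 1) {
  stopifnot(inherits(ac, "allelic_counts"),
            inherits(model, "conversion_model"))
  set.seed(seed)
  n_genes <- nrow(ac$maternal)
  n_cells <- ncol(ac$maternal)
  gene_names <- ac$coords$gene
  cell_names <- colnames(ac$maternal) %||% sprintf("cell%04d",
                                                   seq_len(n_cells))
  blocks <- list()
  for (allele in c("maternal", "paternal")) {
    new_mat <- ac[[allele]]
    mean_new <- pmax(rowMeans(new_mat), 1e-3)
    old_mat <- matrix(stats::rpois(n_genes * n_cells,
                                   rep(mean_new * old_total_factor,
                                       n_cells)),
                      n_genes, n_cells)
    for (is_new in c(TRUE, FALSE)) {
      m <- if (is_new) new_mat else old_mat
      tot <- sum(m)
      if (tot == 0) next
      gene_idx <- rep(rep(seq_len(n_genes), n_cells), as.vector(m))
      cell_idx <- rep(rep(seq_len(n_cells), each = n_genes), as.vector(m))
      n_conv <- pmax(1L, as.integer(round(stats::rlnorm(tot, site_meanlog,
                                                        site_sdlog))))
      p_conv <- if (is_new) model$pc else model$pe
      blocks[[length(blocks) + 1L]] <- data.frame(
        cell = cell_names[cell_idx], gene = gene_names[gene_idx],
        allele_true = allele, is_new_true = is_new,
        n_convertible = n_conv,
        n_converted = stats::rbinom(tot, n_conv, p_conv),
        n_snp = stats::rpois(tot, snp_mean), stringsAsFactors = FALSE)
    }
  }
  mol <- do.call(rbind, blocks)
  if (is.null(mol)) {
    return(data.frame(cell = character(0), gene = character(0),
                      umi = character(0), allele_true = character(0),
                      is_new_true = logical(0), n_convertible = integer(0),
                      n_converted = integer(0), n_maternal = integer(0),
                      n_paternal = integer(0)))
  }
  mol$n_maternal <- ifelse(mol$allele_true == "maternal", mol$n_snp, 0L)
  mol$n_paternal <- ifelse(mol$allele_true == "paternal", mol$n_snp, 0L)
  mol$n_snp <- NULL
  mol$umi <- sprintf("umi%07d", seq_len(nrow(mol)))
  rownames(mol) <- NULL
  mol[, c("cell", "gene", "umi", "allele_true", "is_new_true",
          "n_convertible", "n_converted", "n_maternal", "n_paternal")]
}
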