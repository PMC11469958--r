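# probability vector for likelihood evaluation; `distribution` selects the
# transient PMF or its long-time (Poisson-beta) limit.  "auto" switches to
# the limit when the window is many degradation half-lives long, where the
# two agree far below likelihood precision.
lik_pmf_vector <- function(params, label_time, n_min, distribution = "auto",
                           tol = 1e-10) {
  if (distribution == "auto") {
    distribution <- if (params$k_d * label_time > 27.6) "steady" else
      "transient"
  }
  if (distribution == "steady") {
    p <- steady_pmf_quad(params, n_min = n_min)
    if (length(p) < n_min + 1L) p <- c(p, rep(0, n_min + 1L - length(p)))
    p
  } else {
    pmf_vector(params, label_time, n_min = n_min, tol = tol,
               tail_floor = 1e-9)
  }
}

#' Maximum-likelihood fit of telegraph kinetics to new-RNA counts
#'
#' Maximises the labelled-count log-likelihood over `(k_on, k_syn, k_off)` in
#' log-parameter space with box bounds (defaulting to the lookup-grid axis
#' ranges), using `L-BFGS-B` started from `init`; `k_d` stays fixed.
#'
#' @param counts Non-negative integer vector of per-cell new-RNA counts.
#' @param init A [kinetic_params()] object inside the bounds (typically from
#'   [initialize_parameters()]).
#' @param label_time Labelling window in hours.
#' @param k_d Fixed degradation rate per hour.
#' @param bounds List with `kon`, `ksyn`, `koff` ranges (length-2 vectors).
#' @param distribution `"auto"` (default), `"transient"` or `"steady"`;
#'   `"auto"` evaluates the likelihood through the stationary Poisson-beta
#'   limit when `k_d * label_time` is large enough that the transient and
#'   stationary distributions are numerically identical.
#' @param engine_tol Integrator tolerance for likelihood PMF evaluations.
#' @param maxit Maximum optimizer iterations.
#' @return A list of class `mle_fit`: `params`, `logLik`, `init_logLik`,
#'   `status` (`"ok"` or `"failed"`), `at_bound` (per-parameter logical) and
#'   `convergence` (optimizer code).
#' @export
fit_mle <- function(counts, init, label_time, k_d,
                    bounds = list(kon = c(0.002, 50), ksyn = c(1, 200),
                                  koff = c(0.25, 500)),
                    distribution = "auto", engine_tol = 1e-9, maxit = 200) {
  init <- as_kinetic_params(init)
  counts <- as.integer(counts)
  failed <- function(reason) {
    structure(list(params = NULL, logLik = NA_real_, init_logLik = NA_real_,
                   status = "failed", reason = reason,
                   at_bound = c(kon = NA, ksyn = NA, koff = NA),
                   convergence = NA_integer_), class = "mle_fit")
  }
  if (all(counts == 0)) return(failed("all counts zero"))
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  lo <- log(c(bounds$kon[1], bounds$ksyn[1], bounds$koff[1]))
  hi <- log(c(bounds$kon[2], bounds$ksyn[2], bounds$koff[2]))
  par0 <- clamp(log(c(init$k_on, init$k_syn, init$k_off)), lo, hi)
  n_min <- max(counts)
  negll <- function(par) {
    params <- kinetic_params(exp(par[1]), exp(par[3]), exp(par[2]), k_d)
    p <- tryCatch(
      lik_pmf_vector(params, label_time, n_min, distribution, engine_tol),
      error = function(e) NULL)
    if (is.null(p)) return(1e10)
    .negll_tab(tab, p[seq_along(tab)], 1e-14)
  }
  ll0 <- -negll(par0)
  opt <- tryCatch(
    stats::optim(par0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) return(failed("optimizer error"))
  if (opt$convergence != 0) return(failed("optimizer non-convergence"))
  # monotonicity guarantee: never return a fit worse than its initialisation
  if (-opt$value < ll0) {
    opt$par <- par0
    opt$value <- -ll0
  }
  eps <- 1e-6
  at_bound <- (opt$par <= lo + eps) | (opt$par >= hi - eps)
  names(at_bound) <- c("kon", "ksyn", "koff")
  structure(list(
    params = kinetic_params(exp(opt$par[1]), exp(opt$par[3]),
                            exp(opt$par[2]), k_d),
    logLik = -opt$value, init_logLik = ll0, status = "ok",
    reason = NA_character_, at_bound = at_bound,
    convergence = opt$convergence), class = "mle_fit")
}

fit_bounds_from_table <- function(table) {
  axes <- attr(table, "axes")
  list(kon = range(axes$kon), ksyn = range(axes$ksyn),
       koff = range(axes$koff))
}

# one initialize + fit pass; returns an mle_fit (possibly failed) plus the
# initialisation status
init_and_fit <- function(counts, table, label_time, k_d,
                         distribution = "auto", engine_tol = 1e-9) {
  stats_g <- compute_summary_stats(counts)
  ini <- initialize_parameters(stats_g, table)
  if (ini$status != "ok") {
    return(list(fit = NULL, init = ini, stats = stats_g))
  }
  fit <- fit_mle(counts, ini$params, label_time, k_d,
                 bounds = fit_bounds_from_table(table),
                 distribution = distribution, engine_tol = engine_tol)
  list(fit = fit, init = ini, stats = stats_g)
}

#' Bootstrap robustness assessment for one gene
#'
#' Resamples cells with replacement `n_boot` times, re-runs initialisation
#' and maximum-likelihood fitting on each resample, and reports per-parameter
#' quartiles together with robustness flags. A parameter is robust when the
#' difference between its upper and lower quartile (on the natural-log scale
#' by default) is below `quartile_threshold` and when fewer than half of the
#' bootstrap inferences failed. A bootstrap inference counts as failed when
#' the optimizer fails or when the result lies on the grid boundary.
#'
#' @inheritParams fit_mle
#' @param table A `lookup_table` used for per-resample initialisation.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; results are deterministic given it.
#' @param quartile_threshold Robustness threshold on the quartile spread.
#' @param quartile_scale `"log"` (default) or `"linear"` scale on which the
#'   spread is measured.
#' @return A list of class `gene_bootstrap`: `quartiles` (data.frame with
#'   q25/q50/q75 per parameter), `iqr` (on the chosen scale), `robust`
#'   (named logical), `fail_fraction`, `n_boot`, `seed`.
#' @export
bootstrap_gene <- function(counts, table, label_time = 2, k_d = 0.065,
                           n_boot = 50, seed = 1, quartile_threshold = 2,
                           quartile_scale = c("log", "linear"),
                           distribution = "auto", engine_tol = 1e-9) {
  stopifnot(n_boot >= 2)
  quartile_scale <- match.arg(quartile_scale)
  set.seed(seed)
  n <- length(counts)
  est <- matrix(NA_real_, n_boot, 3,
                dimnames = list(NULL, c("k_on", "k_syn", "k_off")))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    res <- init_and_fit(counts[sample.int(n, n, replace = TRUE)], table,
                        label_time, k_d, distribution, engine_tol)
    bad <- is.null(res$fit) || res$fit$status != "ok" ||
      any(res$fit$at_bound)
    if (bad) {
      failures <- failures + 1L
    } else {
      est[b, ] <- c(res$fit$params$k_on, res$fit$params$k_syn,
                    res$fit$params$k_off)
    }
  }
  fail_fraction <- failures / n_boot
  qs <- apply(est, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  })
  iqr <- vapply(colnames(est), function(p) {
    x <- est[, p][!is.na(est[, p])]
    if (length(x) == 0) return(NA_real_)
    if (quartile_scale == "log") x <- log(x)
    diff(stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
  }, 0)
  robust <- !is.na(iqr) & iqr < quartile_threshold & fail_fraction < 0.5
  structure(list(
    quartiles = data.frame(param = colnames(est), q25 = qs[1, ],
                           q50 = qs[2, ], q75 = qs[3, ], row.names = NULL),
    iqr = iqr, robust = robust, fail_fraction = fail_fraction,
    n_boot = n_boot, seed = seed, quartile_scale = quartile_scale,
    quartile_threshold = quartile_threshold), class = "gene_bootstrap")
}

#' Full per-gene inference
#'
#' Orchestrates the inference pipeline for one gene: summary statistics,
#' lookup-table initialisation, bounded maximum-likelihood fitting,
#' bootstrap robustness assessment and derived kinetics.
#'
#' @inheritParams bootstrap_gene
#' @param bootstrap Run the bootstrap stage (default TRUE).
#' @return A list of class `gene_inference` with `status` (`"ok"`,
#'   `"excluded"`, `"boundary-excluded"` or `"failed"`), `estimates`
#'   ([kinetic_params()] or `NULL`), `derived`, `stats`, `init`, `fit`,
#'   `bootstrap`.
#' @export
infer_gene <- function(counts, table, label_time = 2, k_d = 0.065, seed = 1,
                       n_boot = 50, bootstrap = TRUE, distribution = "auto",
                       engine_tol = 1e-9) {
  res <- init_and_fit(counts, table, label_time, k_d, distribution,
                      engine_tol)
  out <- list(status = NULL, estimates = NULL, derived = NULL,
              stats = res$stats, init = res$init, fit = res$fit,
              bootstrap = NULL, seed = seed)
  if (res$init$status != "ok") {
    out$status <- if (res$init$status == "boundary-excluded")
      "boundary-excluded" else
        if (identical(res$init$reason, "no expressing cells")) "failed" else
          "excluded"
    return(structure(out, class = "gene_inference"))
  }
  if (res$fit$status != "ok") {
    out$status <- "failed"
    return(structure(out, class = "gene_inference"))
  }
  out$estimates <- res$fit$params
  out$derived <- derived_kinetics(res$fit$params)
  if (bootstrap) {
    out$bootstrap <- bootstrap_gene(counts, table, label_time, k_d,
                                    n_boot = n_boot, seed = seed,
                                    distribution = distribution,
                                    engine_tol = engine_tol)
  }
  out$status <- "ok"
  structure(out, class = "gene_inference")
}

gene_inference_row <- function(g, name) {
  est <- g$estimates
  der <- g$derived
  rob <- if (!is.null(g$bootstrap)) g$bootstrap$robust else
    c(k_on = NA, k_syn = NA, k_off = NA)
  data.frame(gene = name, status = g$status,
             k_on = est$k_on %||% NA_real_, k_syn = est$k_syn %||% NA_real_,
             k_off = est$k_off %||% NA_real_, k_d = est$k_d %||% NA_real_,
             occupancy = der$occupancy %||% NA_real_,
             burst_size = der$burst_size %||% NA_real_,
             burst_frequency = der$burst_frequency %||% NA_real_,
             expression_rate = der$expression_rate %||% NA_real_,
             robust_k_on = rob[["k_on"]], robust_k_syn = rob[["k_syn"]],
             robust_k_off = rob[["k_off"]],
             frac_expressing = g$stats$frac_expressing,
             mean_expressing = g$stats$mean_expressing,
             cv_expressing = g$stats$cv_expressing,
             stringsAsFactors = FALSE)
}

#' Inference across a gene-by-cell count matrix
#'
#' Runs [infer_gene()] for every row of a gene-by-cell matrix of new-RNA
#' counts and returns a tidy per-gene results table.
#'
#' @param mat Integer matrix, genes in rows, cells in columns.
#' @inheritParams infer_gene
#' @return A data.frame, one row per gene.
#' @export
infer_genes <- function(mat, table, label_time = 2, k_d = 0.065, seed = 1,
                        n_boot = 50, bootstrap = FALSE,
                        distribution = "auto", engine_tol = 1e-9) {
  stopifnot(is.matrix(mat))
  genes <- rownames(mat) %||% paste0("gene", seq_len(nrow(mat)))
  rows <- lapply(seq_len(nrow(mat)), function(r) {
    g <- infer_gene(mat[r, ], table, label_time, k_d,
                    seed = seed + r, n_boot = n_boot, bootstrap = bootstrap,
                    distribution = distribution, engine_tol = engine_tol)
    gene_inference_row(g, genes[r])
  })
  do.call(rbind, rows)
}

#' Split-half decorrelated inference
#'
#' Randomly partitions the cells into two equal halves, infers kinetics
#' independently on each half, and reports the matrix of Spearman rank
#' correlations (with Benjamini-Hochberg adjusted two-sided p-values)
#' between half-1 and half-2 quantities. Correlating parameters across
#' independent halves removes the spurious coupling that joint inference on
#' shared cells induces between `k_syn` and `k_off`.
#'
#' @inheritParams infer_genes
#' @param seed Seed controlling the (deterministic) partition.
#' @return A list of class `split_half` with `half1`, `half2` (per-gene
#'   tables), `correlation` and `p_adjusted` matrices (half-1 variables in
#'   rows, half-2 in columns), `genes_used` and `cells` (the partition).
#' @export
split_half_analysis <- function(mat, table, label_time = 2, k_d = 0.065,
                                seed = 1, bootstrap = FALSE,
                                distribution = "auto", engine_tol = 1e-9) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  set.seed(seed)
  n <- ncol(mat)
  half1_cells <- sort(sample.int(n, floor(n / 2)))
  half2_cells <- setdiff(seq_len(n), half1_cells)
  h1 <- infer_genes(mat[, half1_cells, drop = FALSE], table, label_time,
                    k_d, seed = seed * 2L + 1L, bootstrap = bootstrap,
                    distribution = distribution, engine_tol = engine_tol)
  h2 <- infer_genes(mat[, half2_cells, drop = FALSE], table, label_time,
                    k_d, seed = seed * 2L + 2L, bootstrap = bootstrap,
                    distribution = distribution, engine_tol = engine_tol)
  ok <- which(h1$status == "ok" & h2$status == "ok")
  vars <- c("k_on", "k_syn", "k_off", "burst_size", "frac_expressing",
            "mean_expressing", "cv_expressing")
  cor_mat <- matrix(NA_real_, length(vars), length(vars),
                    dimnames = list(half1 = vars, half2 = vars))
  p_mat <- cor_mat
  for (a in vars) {
    for (b in vars) {
      x <- h1[[a]][ok]
      y <- h2[[b]][ok]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) >= 3) {
        ct <- suppressWarnings(
          stats::cor.test(x[keep], y[keep], method = "spearman",
                          exact = FALSE))
        cor_mat[a, b] <- unname(ct$estimate)
        p_mat[a, b] <- ct$p.value
      }
    }
  }
  p_adj <- matrix(stats::p.adjust(p_mat, method = "BH"), nrow(p_mat),
                  dimnames = dimnames(p_mat))
  structure(list(half1 = h1, half2 = h2, correlation = cor_mat,
                 p_adjusted = p_adj, genes_used = ok,
                 cells = list(half1 = half1_cells, half2 = half2_cells),
                 seed = seed), class = "split_half")
}

#' Export a per-gene inference table as TSV
#'
#' @param results Data.frame from [infer_genes()].
#' @param path Output path.
#' @param seed Seed echoed into the file header.
#' @return The path, invisibly.
#' @export
write_inference_tsv <- function(results, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(list(kind = "gene_inference"), seed = seed), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
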