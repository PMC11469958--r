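#' Default parameter grid for the inference-bias experiment
#'
#' Low, middle and high values of each rate's observed distribution:
#' `k_on` 0.2 / 0.8944 / 4, `k_syn` 10 / 22.36 / 50 and `k_off` 30 / 77.46 /
#' 200 per hour (27 combinations).
#'
#' @return A data.frame with columns `k_on`, `k_syn`, `k_off`.
#' @export
bias_value_grid <- function() {
  expand.grid(k_on = c(0.2, 0.8944, 4), k_syn = c(10, 22.36, 50),
              k_off = c(30, 77.46, 200))
}

#' Simulated bias of kinetic inference from pulse-labelled vs steady-state counts
#'
#' For every combination of `value_grid` and each labelling time in `times`,
#' samples `n_reps` count tables of `n_cells` cells from the model count
#' distribution and re-infers the parameters (lookup initialisation followed
#' by maximum likelihood). A 2-h window represents new-RNA profiling; a
#' 1,000-h window represents the steady-state (total RNA) distribution, on
#' which synthesis and off rates are not separately identifiable.
#'
#' @param table A `lookup_table` for initialisation (its `k_d` and axis
#'   bounds are used for fitting).
#' @param value_grid Data.frame of true parameter combinations
#'   (default [bias_value_grid()]).
#' @param n_cells Cells per simulated count table.
#' @param n_reps Simulations per combination (the published experiment used
#'   100).
#' @param k_d Degradation rate per hour.
#' @param times Labelling times in hours, typically `c(2, 1000)`.
#' @param seed Integer seed.
#' @return A data.frame of class `bias_experiment`: one row per
#'   combination x time x replicate with true values, estimates, status and
#'   `log_ratio_*` columns (log estimate/truth).
#' @export
bias_experiment <- function(table, value_grid = bias_value_grid(),
                            n_cells = 4000, n_reps = 100, k_d = 0.065,
                            times = c(2, 1000), seed = 1) {
  stopifnot(inherits(table, "lookup_table"), n_reps >= 1)
  set.seed(seed)
  out <- vector("list", nrow(value_grid) * length(times) * n_reps)
  idx <- 0L
  for (combo in seq_len(nrow(value_grid))) {
    truth <- kinetic_params(value_grid$k_on[combo], value_grid$k_off[combo],
                            value_grid$k_syn[combo], k_d)
    for (t in times) {
      steady_arm <- k_d * t > 27.6
      p <- if (steady_arm) steady_state_pmf(truth)$probs else
        pmf_vector(truth, t, tol = 1e-11)
      for (rep in seq_len(n_reps)) {
        counts <- sample.int(length(p), n_cells, replace = TRUE,
                             prob = p) - 1L
        res <- if (steady_arm) {
          # the lookup table indexes pulse-labelled statistics; the
          # steady-state arm starts from the true parameters instead (the
          # most favourable initialisation - the synthesis/off-rate
          # coupling it demonstrates arises from the likelihood itself)
          list(fit = fit_mle(counts, truth, t, k_d,
                             bounds = fit_bounds_from_table(table),
                             distribution = "steady"),
               init = list(status = "truth-init"))
        } else {
          init_and_fit(counts, table, t, k_d)
        }
        fitted <- !is.null(res$fit) && res$fit$status == "ok"
        # a result pinned to the optimization box is a boundary failure,
        # the same failure definition the bootstrap applies
        at_bound <- fitted && any(res$fit$at_bound)
        ok <- fitted && !at_bound
        est <- if (ok) res$fit$params else
          list(k_on = NA_real_, k_syn = NA_real_, k_off = NA_real_)
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          combo = combo, label_time = t, rep = rep,
          k_on_true = truth$k_on, k_syn_true = truth$k_syn,
          k_off_true = truth$k_off,
          k_on_est = est$k_on, k_syn_est = est$k_syn,
          k_off_est = est$k_off,
          status = if (ok) "ok" else if (at_bound) "at-bound" else
            (res$init$status %||% "failed"),
          log_ratio_k_on = log(est$k_on / truth$k_on),
          log_ratio_k_syn = log(est$k_syn / truth$k_syn),
          log_ratio_k_off = log(est$k_off / truth$k_off))
      }
    }
  }
  structure(do.call(rbind, out),
            class = c("bias_experiment", "data.frame"),
            n_cells = n_cells, n_reps = n_reps, k_d = k_d, seed = seed)
}

#' Summarise a bias experiment
#'
#' Per combination and labelling time: median log-ratio per parameter, the
#' dip-test p-value for unimodality of each estimate distribution, and the
#' fraction of failed inferences.
#'
#' @param bias A `bias_experiment` data.frame.
#' @param dip_n_mc Monte-Carlo replicates for the dip null.
#' @return A data.frame, one row per combination x time.
#' @export
summarize_bias <- function(bias, dip_n_mc = 1000) {
  combos <- unique(bias[, c("combo", "label_time")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sel <- bias$combo == combos$combo[r] &
      bias$label_time == combos$label_time[r]
    sub <- bias[sel & bias$status == "ok", ]
    dip_p <- function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 8) return(NA_real_)
      dip_test(x, n_mc = dip_n_mc)$p.value
    }
    data.frame(
      combo = combos$combo[r], label_time = combos$label_time[r],
      n_ok = nrow(sub), fail_fraction = 1 - nrow(sub) / sum(sel),
      median_log_ratio_k_on = stats::median(sub$log_ratio_k_on),
      median_log_ratio_k_syn = stats::median(sub$log_ratio_k_syn),
      median_log_ratio_k_off = stats::median(sub$log_ratio_k_off),
      dip_p_k_on = dip_p(sub$log_ratio_k_on),
      dip_p_k_syn = dip_p(sub$log_ratio_k_syn),
      dip_p_k_off = dip_p(sub$log_ratio_k_off))
  })
  do.call(rbind, rows)
}

#' Cross-replicate coupling of synthesis and off-rate errors
#'
#' Pearson correlation, per combination and labelling time, between
#' `log(k_syn)` and `log(k_off)` estimates across replicates. Strong
#' positive coupling in the steady-state arm (the two rates only enter
#' through their ratio there) contrasts with the pulse-labelled arm.
#'
#' @param bias A `bias_experiment` data.frame.
#' @return A data.frame with `combo`, `label_time`, `cor_syn_off`.
#' @export
bias_syn_off_coupling <- function(bias) {
  combos <- unique(bias[, c("combo", "label_time")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sub <- bias[bias$combo == combos$combo[r] &
                  bias$label_time == combos$label_time[r] &
                  bias$status == "ok", ]
    cc <- if (nrow(sub) >= 5)
      stats::cor(log(sub$k_syn_est), log(sub$k_off_est)) else NA_real_
    data.frame(combo = combos$combo[r],
               label_time = combos$label_time[r], cor_syn_off = cc)
  })
  do.call(rbind, rows)
}
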