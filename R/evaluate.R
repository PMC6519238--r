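# Ranking evaluation against ground truth: average-precision PR-AUC and
# Spearman rank correlation, plus a replicated scenario-study driver.

#' Area under the precision-recall curve (average precision)
#'
#' Computes PR-AUC with the step-wise average-precision estimator: ranks are
#' swept over the distinct score values in descending order, and each true
#' positive contributes the precision at its group boundary; the sum is
#' divided by the number of positives. Tied scores are processed as one
#' group and share the group-level precision. Average precision avoids the
#' optimistic bias of linear interpolation in precision-recall space. If all
#' scores are equal the curve degenerates to a single group and the value is
#' the prevalence, the expected performance of a random classifier.
#'
#' @param abs_scores numeric score vector (larger = ranked higher).
#' @param truth logical (or 0/1) vector of true labels; at least one
#'   positive required.
#' @return PR-AUC in [0, 1].
#' @examples
#' precision_recall_auc(c(0.9, 0.8, 0.1), c(TRUE, FALSE, TRUE))  # 5/6
#' @export
precision_recall_auc <- function(abs_scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(abs_scores) == length(truth))
  P <- sum(truth)
  if (P == 0) stop("no positive labels: PR-AUC undefined")

  ord <- order(abs_scores, decreasing = TRUE)
  s <- abs_scores[ord]
  y <- truth[ord]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp_g <- tapply(as.numeric(y), grp, sum)
  n_g <- tabulate(grp)
  cum_tp <- cumsum(tp_g)
  cum_n <- cumsum(n_g)
  prec_g <- cum_tp / cum_n
  sum(tp_g * prec_g) / P
}

#' Spearman rank correlation between true and estimated absolute effects
#'
#' @param true_abs_beta absolute true coefficients.
#' @param abs_scores absolute estimated scores.
#' @return Spearman correlation in [-1, 1] (average ranks for ties).
#' @export
rank_correlation <- function(true_abs_beta, abs_scores) {
  stopifnot(length(true_abs_beta) == length(abs_scores))
  if (stats::sd(true_abs_beta) == 0 || stats::sd(abs_scores) == 0)
    stop("zero variance: rank correlation undefined")
  stats::cor(true_abs_beta, abs_scores, method = "spearman")
}

#' Build a scenario grid for a simulation study
#'
#' Convenience constructor: expands the supplied parameter values into a
#' scenario table (one row per scenario) consumed by \code{\link{run_study}}.
#'
#' @param n,d,rel_var,exp_var,cens_rate,signal_block,family,snr scenario
#'   parameters; vectors are crossed.
#' @return data.frame with one row per scenario.
#' @export
scenario_grid <- function(n = 500, d = 99, rel_var = 0.1, exp_var = 0.5,
                          cens_rate = 0.25, signal_block = 1L,
                          family = "lognormal", snr = 0.5) {
  expand.grid(n = n, d = d, rel_var = rel_var, exp_var = exp_var,
              cens_rate = cens_rate, signal_block = signal_block,
              family = family, snr = snr,
              stringsAsFactors = FALSE)
}

#' Run a replicated simulation study
#'
#' For every scenario and replicate: draw a dataset, compute CARS and Cox
#' scores, and evaluate both rankings against the set of influential
#' covariates by PR-AUC and against the true absolute coefficients by
#' Spearman rank correlation. Per-scenario designs are calibrated once;
#' per-replicate seeds are derived deterministically from \code{base_seed},
#' so the full results table is reproducible.
#'
#' @param scenarios data.frame from \code{\link{scenario_grid}} (or with the
#'   same columns).
#' @param replications replicates per scenario (default 10).
#' @param base_seed integer base seed.
#' @param pilot_size pilot size for design calibration (default 1e5).
#' @param admin_quantile administrative-censoring quantile (default 0.90).
#' @param methods character subset of c("cars", "cox").
#' @return data.frame of class \code{study_results}: one row per
#'   (scenario, replicate, method) with columns \code{pr_auc} and
#'   \code{rank_corr} plus the scenario descriptors.
#' @export
run_study <- function(scenarios, replications = 10L, base_seed = 1L,
                      pilot_size = 1e5, admin_quantile = 0.90,
                      methods = c("cars", "cox")) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) >= 1,
            replications >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  n_scn <- nrow(scenarios)
  seeds <- matrix(derive_seeds(base_seed, n_scn * (replications + 1L)),
                  nrow = n_scn)
  rows <- vector("list", n_scn * replications * length(methods))
  ri <- 0L
  for (i in seq_len(n_scn)) {
    scn <- scenarios[i, ]
    design <- simulation_design(
      n = scn$n, d = scn$d, rel_var = scn$rel_var,
      signal_block = scn$signal_block, family = scn$family,
      exp_var = if (is.null(scn$exp_var)) 0.5 else scn$exp_var,
      snr = if (is.null(scn$snr)) 0.5 else scn$snr,
      cens_rate = scn$cens_rate,
      admin_quantile = admin_quantile, seed = seeds[i, 1],
      pilot_size = pilot_size
    )
    for (r in seq_len(replications)) {
      rep_seed <- seeds[i, r + 1L]
      ds <- simulate_dataset(design, seed = rep_seed)
      score_sets <- list()
      if ("cars" %in% methods)
        score_sets$cars <- cars_scores(ds$sample)$scores
      if ("cox" %in% methods)
        score_sets$cox <- cox_scores(ds$sample)$z_scores
      for (m in names(score_sets)) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          scenario = i, n = scn$n, d = scn$d, rel_var = scn$rel_var,
          exp_var = scn$exp_var, cens_rate = scn$cens_rate,
          signal_block = scn$signal_block, family = scn$family,
          replicate = r, seed = rep_seed, method = m,
          pr_auc = precision_recall_auc(abs(score_sets[[m]]),
                                        ds$influential_mask),
          rank_corr = rank_correlation(abs(ds$beta_true),
                                       abs(score_sets[[m]])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  class(out) <- c("study_results", "data.frame")
  out
}

#' Summarize study results per scenario and method
#'
#' @param results output of \code{\link{run_study}}.
#' @return data.frame of per-scenario, per-method medians and interquartile
#'   ranges of PR-AUC and rank correlation.
#' @export
summarize_study <- function(results) {
  stopifnot(is.data.frame(results))
  key <- interaction(results$scenario, results$method, drop = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(
      scenario = g$scenario[1], n = g$n[1], d = g$d[1],
      rel_var = g$rel_var[1], exp_var = g$exp_var[1],
      cens_rate = g$cens_rate[1], signal_block = g$signal_block[1],
      family = g$family[1], method = g$method[1],
      replicates = nrow(g),
      pr_auc_median = stats::median(g$pr_auc),
      pr_auc_iqr = stats::IQR(g$pr_auc),
      rank_corr_median = stats::median(g$rank_corr),
      rank_corr_iqr = stats::IQR(g$rank_corr),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$scenario, out$method), ]
}
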