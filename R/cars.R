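#' IPC-weighted mean and variance of log survival time
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param weights IPC weights from \code{\link{ipc_weights}}.
#' @return list with \code{ybar_w} (weighted mean of log times) and
#'   \code{s2_yw} (weighted variance). Both use the 1/n normalization of the
#'   IPC-weighted moment estimators, not 1/sum(w) and not 1/(n-1).
#' @export
weighted_mean_var_logT <- function(sample, weights) {
  assert_sample(sample)
  if (length(weights) != sample$n) stop("weights must have length n")
  if (all(weights == 0)) stop("no uncensored observations: all weights are zero")
  n <- sample$n
  y <- log(sample$times)
  ybar_w <- sum(weights * y) / n
  s2_yw <- sum(weights * (y - ybar_w)^2) / n
  list(ybar_w = ybar_w, s2_yw = s2_yw)
}

#' IPC-weighted covariance vector between covariates and log survival time
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param weights IPC weights.
#' @param ybar_w weighted mean of the log times (from
#'   \code{\link{weighted_mean_var_logT}}).
#' @param means unweighted covariate column means; computed if missing.
#'   Covariate centering is unweighted because covariate values are observed
#'   regardless of censoring.
#' @return numeric vector of length d.
#' @export
weighted_cov_vector <- function(sample, weights, ybar_w, means = NULL) {
  assert_sample(sample)
  if (length(weights) != sample$n) stop("weights must have length n")
  if (all(weights == 0)) stop("no uncensored observations: all weights are zero")
  X <- sample$covariates
  if (is.null(means)) means <- colMeans(X)
  y <- log(sample$times)
  wy <- weights * (y - ybar_w)
  drop(crossprod(X, wy)) / sample$n - means * sum(wy) / sample$n
}

#' Marginal IPC-weighted correlations
#'
#' Combines the weighted covariance vector with the unweighted covariate
#' variances (n - 1 divisor) and the weighted outcome variance (1/n
#' normalization) into the marginal correlation vector. The two
#' normalizations differ deliberately: the covariate moments are the plain
#' sample estimators while the outcome moments must be IPC-weighted, and the
#' mismatch (a factor sqrt((n-1)/n) in the uncensored case) vanishes
#' asymptotically.
#'
#' @param cov_vec weighted covariance vector, length d.
#' @param s2_x unweighted covariate sample variances (n - 1 divisor), > 0.
#' @param s2_yw weighted variance of the log outcome, > 0.
#' @return correlation vector clamped to [-1, 1]; a warning is issued if
#'   clamping was needed (possible in small samples with large weights).
#' @export
marginal_correlations <- function(cov_vec, s2_x, s2_yw) {
  if (s2_yw <= 0) stop("degenerate outcome: weighted variance of log time is zero")
  if (any(s2_x <= 0)) stop("covariate variances must be positive")
  r <- cov_vec / sqrt(s2_x * s2_yw)
  out_of_range <- abs(r) > 1
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " marginal correlation(s) outside [-1, 1] were clamped")
    r <- pmin(1, pmax(-1, r))
  }
  r
}

#' Correlation-adjusted survival (CARS) scores
#'
#' Computes the CARS score of every covariate against a right-censored
#' survival outcome: theta_hat = R_shrink^{-1/2} R_XY, where R_XY is the
#' vector of IPC-weighted marginal correlations between the covariates and
#' log survival time, and R_shrink is the shrinkage estimate of the
#' covariate correlation matrix. The scores measure the association between
#' the outcome and the decorrelated (whitened) covariates; ranking them by
#' magnitude gives a correlation-adjusted variable importance ordering.
#'
#' @param sample a \code{\link{survival_sample}} with at least one event and
#'   no constant covariates.
#' @param lambda shrinkage intensity override in [0, 1]; estimated from the
#'   data by \code{\link{shrinkage_intensity}} when \code{NULL} (default).
#'   \code{lambda = 1} reduces the scores to the marginal correlations.
#' @param censoring_weights optional numeric vector of externally supplied
#'   per-observation censoring-survival evaluations, passed through to
#'   \code{\link{ipc_weights}} (conditional-censoring injection point).
#' @return An object of class \code{cars_result}: list with \code{scores}
#'   (theta_hat, named), \code{abs_rank} (1 = largest magnitude, ties broken
#'   by column order), \code{marginal_corr} (R_XY before decorrelation),
#'   \code{lambda_used} and \code{n_effective} (sum of the IPC weights).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3)
#' t <- exp(X[, 1] + rnorm(100))
#' s <- survival_sample(t, rep(1, 100), X)
#' cars_scores(s)$scores
#' @export
cars_scores <- function(sample, lambda = NULL, censoring_weights = NULL) {
  assert_sample(sample)
  if (!is.null(censoring_weights)) {
    w <- ipc_weights(sample, censoring_weights)
  } else {
    w <- ipc_weights(sample)
  }
  std <- standardize_columns(sample$covariates)
  mv <- weighted_mean_var_logT(sample, w)
  cov_vec <- weighted_cov_vector(sample, w, mv$ybar_w, means = std$means)
  r_xy <- marginal_correlations(cov_vec, std$sds^2, mv$s2_yw)

  if (is.null(lambda)) lambda <- shrinkage_intensity(std$Xs)
  op <- build_shrink_op(std$Xs, lambda)
  theta <- drop(apply_inv_sqrt(op, r_xy))
  names(theta) <- colnames(sample$covariates)

  structure(list(
    scores = theta,
    abs_rank = rank_by_magnitude(theta),
    marginal_corr = stats::setNames(r_xy, colnames(sample$covariates)),
    lambda_used = lambda,
    n_effective = sum(w)
  ), class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  d <- length(x$scores)
  cat(sprintf("<cars_result> d = %d, lambda = %.4f, effective n = %.1f\n",
              d, x$lambda_used, x$n_effective))
  top <- order(x$abs_rank)[seq_len(min(5L, d))]
  cat("top |score|:", paste(sprintf("%s=%.3f", names(x$scores)[top],
                                    x$scores[top]), collapse = ", "), "\n")
  invisible(x)
}

# rank 1 = largest |score|; ties broken by original column order
rank_by_magnitude <- function(scores) {
  ord <- order(-abs(scores), seq_along(scores))
  rk <- integer(length(scores))
  rk[ord] <- seq_along(scores)
  rk
}

#' Population accelerated-failure-time model
#'
#' Specifies the lognormal AFT data-generating model log T = beta0 + x'beta
#' + eps with multivariate covariates of covariance Sigma and Gaussian noise
#' variance sigma_eps2; the population quantities derived from it serve as
#' the analytic reference for the empirical CARS estimator.
#'
#' @param Sigma covariate covariance matrix, symmetric positive definite.
#' @param beta regression coefficient vector.
#' @param beta0 intercept (irrelevant for correlations; default 0).
#' @param sigma_eps2 noise variance, > 0.
#' @return object of class \code{population_model}.
#' @export
population_model <- function(Sigma, beta, beta0 = 0, sigma_eps2 = 1) {
  Sigma <- as.matrix(Sigma)
  d <- nrow(Sigma)
  stopifnot(ncol(Sigma) == d, length(beta) == d, sigma_eps2 > 0)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(abs(Sigma), 1))
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  structure(list(Sigma = Sigma, beta = as.numeric(beta), beta0 = beta0,
                 sigma_eps2 = sigma_eps2, d = d),
            class = "population_model")
}

#' Population CARS scores under the lognormal AFT model
#'
#' Closed-form target of the empirical CARS estimator: theta =
#' P_X^{-1/2} P_XY with P_X the covariate correlation matrix and P_XY the
#' correlation vector between covariates and log T. Under the lognormal AFT
#' model Cov(x, log T) = Sigma beta and Var(log T) = beta' Sigma beta +
#' sigma_eps2, so everything is available analytically.
#'
#' @param model a \code{\link{population_model}}.
#' @return numeric vector theta of length d, with attribute
#'   \code{explained_variance} = theta' theta, the population proportion of
#'   Var(log T) explained by the best linear predictor.
#' @export
population_cars <- function(model) {
  stopifnot(inherits(model, "population_model"))
  Sigma <- model$Sigma
  beta <- model$beta
  sig_diag <- sqrt(diag(Sigma))
  sigma_y <- sqrt(drop(crossprod(beta, Sigma %*% beta)) + model$sigma_eps2)

  p_xy <- drop(Sigma %*% beta) / (sig_diag * sigma_y)
  P_x <- Sigma / tcrossprod(sig_diag)

  e <- eigen(P_x, symmetric = TRUE)
  if (min(e$values) <= 0) stop("implied correlation matrix is not positive definite")
  inv_sqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  theta <- drop(inv_sqrt %*% p_xy)
  attr(theta, "explained_variance") <- sum(theta^2)
  theta
}
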