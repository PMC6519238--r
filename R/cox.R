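#' Univariate Cox score for a single covariate
#'
#' Fits the one-parameter Cox proportional hazards model by Newton-Raphson
#' maximization of the partial likelihood with Breslow tie handling, and
#' returns the standardized coefficient (Wald Z = beta_hat / se(beta_hat),
#' with the standard error from the observed information).
#'
#' @param x numeric covariate vector, length n.
#' @param times positive observed times.
#' @param status 0/1 event indicators; at least one event required.
#' @param max_iter maximum Newton-Raphson iterations (default 50).
#' @param tol convergence tolerance on the absolute score (default 1e-9).
#' @param z_cap magnitude assigned (with the sign of the diverging
#'   coefficient) when the partial likelihood is monotone, e.g. under
#'   perfect risk-set separation. Default 37.
#' @return list with \code{z}, \code{beta} (fitted log hazard ratio for the
#'   standardized covariate) and \code{converged}. A constant covariate
#'   yields \code{z = 0}.
#' @export
univariate_cox_score <- function(x, times, status, max_iter = 50L,
                                 tol = 1e-9, z_cap = 37) {
  n <- length(x)
  stopifnot(length(times) == n, length(status) == n)
  if (sum(status) < 1) stop("need at least one event")
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0)
    return(list(z = 0, beta = 0, converged = TRUE))
  xs <- (x - mean(x)) / sdx  # z is invariant to affine rescaling of x

  prep <- cox_risk_prep(times, status)
  fit <- cox_newton(xs, prep, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    return(list(z = sign(fit$beta) * z_cap, beta = fit$beta, converged = FALSE))
  }
  se <- 1 / sqrt(fit$info)
  list(z = fit$beta / se, beta = fit$beta, converged = TRUE)
}

#' Univariate Cox scores for every covariate
#'
#' Maps \code{\link{univariate_cox_score}} over the columns of the covariate
#' matrix. This is the classical univariate screening comparator: each
#' covariate is scored in isolation, so dependencies between covariates are
#' ignored by construction.
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param ... passed to \code{\link{univariate_cox_score}}.
#' @return object of class \code{cox_score_vector}: list with \code{z_scores}
#'   (named numeric vector) and \code{converged} (logical vector).
#' @export
cox_scores <- function(sample, ...) {
  assert_sample(sample)
  if (sum(sample$status) < 1) stop("need at least one event")
  prep <- cox_risk_prep(sample$times, sample$status)
  d <- sample$d
  z <- numeric(d)
  conv <- logical(d)
  for (j in seq_len(d)) {
    x <- sample$covariates[, j]
    sdx <- stats::sd(x)
    if (!is.finite(sdx) || sdx == 0) {
      z[j] <- 0; conv[j] <- TRUE
      next
    }
    xs <- (x - mean(x)) / sdx
    fit <- cox_newton(xs, prep, ...)
    if (fit$converged) {
      z[j] <- fit$beta * sqrt(fit$info)
      conv[j] <- TRUE
    } else {
      z[j] <- sign(fit$beta) * 37
      conv[j] <- FALSE
    }
  }
  names(z) <- colnames(sample$covariates)
  structure(list(z_scores = z, converged = conv), class = "cox_score_vector")
}

# Precompute risk-set bookkeeping shared across covariates.
# Observations are sorted by decreasing time so that cumulative sums give
# risk-set totals; tied event times are grouped (Breslow).
cox_risk_prep <- function(times, status) {
  ord <- order(times, decreasing = TRUE)
  ts <- times[ord]
  ds <- status[ord]
  ue <- sort(unique(ts[ds == 1]))          # distinct event times, ascending
  neg_sorted <- sort(-times)
  risk_idx <- findInterval(-ue, neg_sorted)  # #\{times >= u\} per event time
  d_t <- vapply(ue, function(u) sum(ts == u & ds == 1), numeric(1))
  list(ord = ord, event = which(ds == 1), risk_idx = risk_idx, d_t = d_t)
}

# Newton-Raphson for the single-covariate Breslow partial likelihood.
# Returns beta, observed information and convergence flag; divergence
# (monotone likelihood) is reported via converged = FALSE.
cox_newton <- function(xs_unsorted_in_ord = NULL, prep, max_iter = 50L,
                       tol = 1e-9) {
  xs <- xs_unsorted_in_ord[prep$ord]
  x_ev_sum <- sum(xs[prep$event])
  beta <- 0
  info <- NA_real_
  for (iter in seq_len(max_iter)) {
    e <- exp(beta * xs)
    c0 <- cumsum(e)
    c1 <- cumsum(xs * e)
    c2 <- cumsum(xs^2 * e)
    s0 <- c0[prep$risk_idx]
    s1 <- c1[prep$risk_idx]
    s2 <- c2[prep$risk_idx]
    m1 <- s1 / s0
    score <- x_ev_sum - sum(prep$d_t * m1)
    info <- sum(prep$d_t * (s2 / s0 - m1^2))
    if (!is.finite(score) || !is.finite(info) || info <= 1e-12) {
      return(list(beta = beta, info = info, converged = FALSE))
    }
    if (abs(score) < tol) {
      return(list(beta = beta, info = info, converged = TRUE))
    }
    beta <- beta + score / info
    # xs is standardized, so |beta| this large means a hazard ratio beyond
    # e^15 per standard deviation: monotone-likelihood (separation) territory.
    # The flattening tail would otherwise satisfy the score tolerance at a
    # huge beta with near-zero information and report a spurious small z.
    if (abs(beta) > 15) {
      return(list(beta = beta, info = info, converged = FALSE))
    }
  }
  list(beta = beta, info = info, converged = FALSE)
}

#' Breslow partial log-likelihood for a single covariate
#'
#' Exposed mainly for verification: the value of the partial log-likelihood
#' at a given coefficient, with Breslow handling of tied event times.
#'
#' @param beta coefficient value.
#' @param x covariate vector.
#' @param times,status observed times and event indicators.
#' @return scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(beta, x, times, status) {
  prep <- cox_risk_prep(times, status)
  xs <- x[prep$ord]
  e <- exp(beta * xs)
  c0 <- cumsum(e)
  sum(beta * xs[prep$event]) - sum(prep$d_t * log(c0[prep$risk_idx]))
}
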