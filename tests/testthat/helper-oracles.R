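# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (explicit loops, dense
# matrices, exhaustive enumeration) rather than calling package internals.

# product-limit estimate of P(C > t) by an explicit risk-set loop, with
# events ordered before censorings at tied times; returns a step function
bf_censoring_survival <- function(times, status) {
  ut <- sort(unique(times))
  g <- 1
  jumps <- numeric(0)
  vals <- numeric(0)
  alive <- rep(TRUE, length(times))
  for (u in ut) {
    ev <- alive & times == u & status == 1
    alive[ev] <- FALSE           # events leave first
    cs <- alive & times == u & status == 0
    n_cs <- sum(cs)
    if (n_cs > 0) {
      at_risk <- sum(alive)      # censored-at-u still counted at risk
      g <- g * (1 - n_cs / at_risk)
      jumps <- c(jumps, u)
      vals <- c(vals, g)
    }
    alive[cs] <- FALSE
  }
  function(t, left = TRUE) {
    vapply(t, function(ti) {
      keep <- if (left) jumps < ti else jumps <= ti
      if (!any(keep)) 1 else vals[max(which(keep))]
    }, numeric(1))
  }
}

# dense inverse square root of lambda * I + (1 - lambda) * cor(X)
bf_shrink_inv_sqrt <- function(X, lambda) {
  R <- stats::cor(X)
  Rs <- lambda * diag(ncol(X)) + (1 - lambda) * R
  e <- eigen(Rs, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# shrinkage intensity by an explicit double loop over covariate pairs
bf_shrinkage_intensity <- function(X) {
  n <- nrow(X); d <- ncol(X)
  Xs <- scale(X)
  num <- 0; den <- 0
  for (j in seq_len(d)) for (k in seq_len(d)) {
    if (j == k) next
    w <- Xs[, j] * Xs[, k]
    num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
    den <- den + stats::cor(X[, j], X[, k])^2
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

# PR-AUC by exhaustive threshold enumeration: step-wise precision at each
# distinct-score threshold weighted by the recall increment
bf_pr_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  P <- sum(truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  auc <- 0; prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & truth)
    precision <- tp / sum(pred)
    recall <- tp / P
    auc <- auc + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  auc
}

# Breslow partial log-likelihood written independently (per-event risk sums)
bf_cox_loglik <- function(beta, x, times, status) {
  ll <- 0
  for (u in sort(unique(times[status == 1]))) {
    ev <- which(times == u & status == 1)
    risk <- which(times >= u)
    ll <- ll + sum(beta * x[ev]) - length(ev) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# small random survival fixture (with optional ties through rounding)
random_fixture <- function(n, seed, tie_round = NULL) {
  set.seed(seed)
  tt <- rexp(n) + 0.1
  if (!is.null(tie_round)) tt <- round(tt, tie_round) + 0.01
  st <- rbinom(n, 1, 0.7)
  if (all(st == 0)) st[1] <- 1
  list(times = tt, status = st)
}
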