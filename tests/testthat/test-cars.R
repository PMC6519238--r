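test_that("weighted moments reproduce hand arithmetic", {
  X <- matrix(rnorm(3), 3, 1)
  s <- survival_sample(exp(1:3), c(1, 1, 1), X)
  mv <- weighted_mean_var_logT(s, rep(1, 3))
  expect_equal(mv$ybar_w, 2)
  expect_equal(mv$s2_yw, 2 / 3)

  # single event with weight w among n
  s2 <- survival_sample(c(5, 7, 9, 11), c(1, 0, 0, 0), matrix(rnorm(4)))
  mv2 <- weighted_mean_var_logT(s2, c(2.5, 0, 0, 0))
  expect_equal(mv2$ybar_w, 2.5 * log(5) / 4)

  s3 <- survival_sample(rep(4, 3), c(1, 1, 1), X)
  expect_equal(weighted_mean_var_logT(s3, rep(1, 3))$s2_yw, 0)

  expect_error(weighted_mean_var_logT(s, rep(0, 3)), "no uncensored")
})

test_that("weighted covariance vector behaves as a covariance", {
  set.seed(1)
  n <- 40
  y <- rnorm(n)
  s <- survival_sample(exp(y), rep(1, n), cbind(self = y, other = rnorm(n)))
  w <- rep(1, n)
  mv <- weighted_mean_var_logT(s, w)
  cv <- weighted_cov_vector(s, w, mv$ybar_w)
  expect_equal(cv[["self"]], mv$s2_yw, tolerance = 1e-12)

  # the covariate equals its overall mean wherever weights are positive,
  # so the weighted covariance entry is exactly zero
  x <- c(rep(3, 5), 1:5)  # mean(x) = 3
  w0 <- c(rep(1, 5), rep(0, 5))
  s0 <- survival_sample(exp(rnorm(10)), c(rep(1, 5), rep(0, 5)), cbind(x = x))
  mv0 <- weighted_mean_var_logT(s0, w0)
  expect_equal(weighted_cov_vector(s0, w0, mv0$ybar_w)[["x"]], 0)
})

test_that("marginal correlation clamps and matches the mixed-normalization identity", {
  # without censoring the score is Pearson r times sqrt((n-1)/n)
  set.seed(2)
  n <- 30
  x <- rnorm(n)
  t <- exp(0.7 * x + rnorm(n))
  s <- survival_sample(t, rep(1, n), matrix(x, dimnames = list(NULL, "x")))
  res <- cars_scores(s, lambda = 1)
  expect_equal(unname(res$scores), cor(x, log(t)) * sqrt((n - 1) / n),
               tolerance = 1e-12)
  expect_equal(unname(res$scores), unname(res$marginal_corr))

  expect_equal(marginal_correlations(c(0, 0), c(1, 2), 0.5), c(0, 0))
  expect_warning(r <- marginal_correlations(1.004, 1, 1), "clamped")
  expect_equal(r, 1)
  expect_error(marginal_correlations(1, 1, 0), "degenerate outcome")
})

test_that("cars scores are invariant to affine covariate transforms", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4)
  t <- exp(X[, 1] - 0.5 * X[, 2] + rnorm(n))
  st <- rbinom(n, 1, 0.8); st[1] <- 1
  s <- survival_sample(t, st, X)
  base <- cars_scores(s)

  X2 <- X
  X2[, 2] <- 7 * X[, 2] + 3
  s2 <- survival_sample(t, st, X2)
  expect_equal(cars_scores(s2)$scores, base$scores, tolerance = 1e-10)

  X3 <- X
  X3[, 1] <- -X[, 1]
  s3 <- survival_sample(t, st, X3)
  expect_equal(unname(cars_scores(s3)$marginal_corr[1]),
               -unname(base$marginal_corr[1]), tolerance = 1e-10)
})

test_that("abs_rank is a deterministic permutation with column-order ties", {
  set.seed(4)
  X <- matrix(rnorm(50 * 3), 50, 3)
  X[, 3] <- X[, 1]  # duplicate column -> tied |score|
  t <- exp(X[, 1] + rnorm(50))
  s <- survival_sample(t, rep(1, 50), X)
  res <- cars_scores(s, lambda = 1)
  expect_setequal(res$abs_rank, 1:3)
  tied <- which(abs(abs(res$scores) - max(abs(res$scores))) < 1e-12)
  expect_equal(res$abs_rank[tied], sort(res$abs_rank[tied]))
})

test_that("population CARS matches closed forms and the explained-variance identity", {
  m <- population_model(diag(2), c(1, 0), sigma_eps2 = 1)
  th <- population_cars(m)
  expect_equal(unname(th[1:2]), c(1 / sqrt(2), 0), tolerance = 1e-12)
  expect_equal(attr(th, "explained_variance"), 0.5, tolerance = 1e-12)

  expect_equal(as.numeric(population_cars(population_model(diag(3), rep(0, 3)))),
               rep(0, 3))

  # theta' theta equals P_XY' P_X^{-1} P_XY
  set.seed(5)
  A <- matrix(rnorm(16), 4)
  Sigma <- crossprod(A) + diag(4)
  beta <- rnorm(4)
  mod <- population_model(Sigma, beta, sigma_eps2 = 2)
  th2 <- population_cars(mod)
  sig_d <- sqrt(diag(Sigma))
  sigy <- sqrt(drop(crossprod(beta, Sigma %*% beta)) + 2)
  pxy <- drop(Sigma %*% beta) / (sig_d * sigy)
  Px <- Sigma / tcrossprod(sig_d)
  expect_equal(sum(th2^2), drop(crossprod(pxy, solve(Px, pxy))),
               tolerance = 1e-12)

  expect_error(population_model(matrix(c(1, 2, 2, 1), 2), c(1, 1)),
               "positive definite")
})

test_that("population CARS agrees with a Monte-Carlo correlation oracle", {
  rho <- 0.75
  Sigma <- matrix(c(1, rho, rho, 1), 2)
  beta <- c(1, 1)
  v <- drop(crossprod(beta, Sigma %*% beta))
  mod <- population_model(Sigma, beta, sigma_eps2 = v)  # theta' theta = 0.5
  th <- population_cars(mod)
  expect_equal(attr(th, "explained_variance"), 0.5, tolerance = 1e-12)

  set.seed(6)
  n <- 5e5
  Z <- matrix(rnorm(2 * n), n, 2) %*% chol(Sigma)
  y <- drop(Z %*% beta) + rnorm(n, 0, sqrt(v))
  e <- eigen(Sigma, symmetric = TRUE)  # Sigma is already a correlation matrix
  W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  Zdec <- Z %*% t(W)
  mc <- c(cor(Zdec[, 1], y), cor(Zdec[, 2], y))
  expect_equal(unname(th[1:2]), mc, tolerance = 0.005)
})

test_that("empirical scores recover the population scores under censoring", {
  # independent-covariate design with 25% censoring
  des <- simulation_design(n = 20000, d = 6, rel_var = 0.5, signal_block = 0,
                           exp_var = 0.5, cens_rate = 0.25,
                           admin_quantile = NULL, seed = 31, pilot_size = 2e4)
  pop <- population_cars(population_model(des$Sigma, des$beta,
                                          sigma_eps2 = des$sigma_eps2))
  ds <- simulate_dataset(des, seed = 77)
  emp <- cars_scores(ds$sample)$scores
  expect_lt(max(abs(emp - pop)), 0.03)
})

test_that("null covariates get smaller scores as n grows", {
  gap_at <- function(n, seed) {
    des <- simulation_design(n = n, d = 9, rel_var = 1 / 9, signal_block = 1,
                             exp_var = 0.5, cens_rate = 0.25,
                             admin_quantile = NULL, seed = 13,
                             pilot_size = 2e4)
    ds <- simulate_dataset(des, seed = seed)
    sc <- cars_scores(ds$sample)$scores
    pop <- population_cars(population_model(des$Sigma, des$beta,
                                            sigma_eps2 = des$sigma_eps2))
    null_idx <- which(abs(pop) < 1e-10)
    if (length(null_idx) == 0) null_idx <- which(!ds$influential_mask)
    median(abs(sc[null_idx]))
  }
  small <- median(vapply(1:5, function(i) gap_at(500, 100 + i), numeric(1)))
  large <- median(vapply(1:5, function(i) gap_at(5000, 200 + i), numeric(1)))
  expect_lt(large, small)
})
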