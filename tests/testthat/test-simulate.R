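test_that("block correlation matrix honors the block design", {
  raw <- block_correlation_matrix(30, seed = 1, repair = FALSE)
  expect_equal(diag(raw), rep(1, 30))
  sizes <- attr(raw, "block_sizes")
  expect_equal(sizes, rep(10, 3))
  # between-block entries are zero before repair
  expect_true(all(raw[1:10, 11:30] == 0))
  expect_true(all(raw[11:20, 21:30] == 0))
  # within-block magnitudes
  b1 <- raw[1:10, 1:10]
  expect_true(all(abs(b1[upper.tri(b1)]) == 0.25))

  rep1 <- block_correlation_matrix(30, seed = 1)
  ev <- eigen(rep1, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(diag(rep1), rep(1, 30), tolerance = 1e-8)

  # sign balance for a larger matrix
  raw300 <- block_correlation_matrix(300, seed = 2, repair = FALSE)
  b <- raw300[1:100, 1:100]
  frac_pos <- mean(b[upper.tri(b)] > 0)
  expect_gt(frac_pos, 0.45)
  expect_lt(frac_pos, 0.55)

  # uneven d splits as ceiling, ceiling, remainder
  expect_equal(attr(block_correlation_matrix(10, seed = 1, repair = FALSE),
                    "block_sizes"), c(4, 4, 2))
})

test_that("nearest correlation projection fixes indefinite matrices minimally", {
  # valid matrices are fixed points
  A <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(nearest_correlation(A), A, tolerance = 1e-8)

  B <- diag(3)
  B[1, 2] <- B[2, 1] <- 0.99
  B[1, 3] <- B[3, 1] <- 0.99
  B[2, 3] <- B[3, 2] <- -0.99  # indefinite
  expect_lt(min(eigen(B, only.values = TRUE)$values), 0)
  Bfix <- nearest_correlation(B)
  expect_gte(min(eigen(Bfix, only.values = TRUE)$values), -1e-8)
  expect_equal(diag(Bfix), rep(1, 3), tolerance = 1e-8)

  # near-optimality: no coarse uniform shrinkage of the off-diagonals that
  # is PSD comes closer in Frobenius distance
  dist_fix <- sqrt(sum((Bfix - B)^2))
  for (a in seq(0.1, 1, by = 0.05)) {
    Ba <- B * a; diag(Ba) <- 1
    if (min(eigen(Ba, only.values = TRUE)$values) >= -1e-10) {
      expect_gte(sqrt(sum((Ba - B)^2)), dist_fix - 1e-6)
    }
  }

  expect_error(nearest_correlation(matrix(c(1, 2, 3, 1), 2)), "symmetric")
})

test_that("equidistant coefficients span [-0.9, 1]", {
  expect_equal(make_coefficients(2), c(-0.9, 1))
  expect_equal(make_coefficients(1), 1)
  suppressMessages(b20 <- make_coefficients(20))
  expect_equal(diff(b20), rep(0.1, 19))
  expect_equal(b20[10], 0)
  expect_message(make_coefficients(20), "zero")
})

test_that("lognormal noise calibration hits the target explained variance", {
  Sigma <- diag(3)
  beta <- c(1, 0.5, 0)
  v <- drop(crossprod(beta, Sigma %*% beta))
  expect_equal(calibrate_lognormal_noise(Sigma, beta / sqrt(v), 0.5), 1)
  expect_equal(calibrate_lognormal_noise(Sigma, beta, 0.75), v / 3)
  expect_error(calibrate_lognormal_noise(Sigma, rep(0, 3), 0.5), "no signal")

  # Monte-Carlo: realized R^2 of log T on the linear predictor
  s2 <- calibrate_lognormal_noise(Sigma, beta, 0.5)
  set.seed(1)
  n <- 1e5
  lp <- rnorm(n, 0, sqrt(v))
  y <- lp + rnorm(n, 0, sqrt(s2))
  expect_lt(abs(summary(lm(y ~ lp))$r.squared - 0.5), 0.01)
})

test_that("weibull shape calibration matches the closed form and scales", {
  Sigma <- diag(4)
  beta <- c(0.8, -0.4, 0.2, 0)
  v <- drop(crossprod(beta, Sigma %*% beta))
  phi <- calibrate_weibull_shape(Sigma, beta, snr = 0.5, pilot_size = 2e5, seed = 3)
  closed <- pi / sqrt(6 * v / 0.5)
  expect_lt(abs(phi - closed) / closed, 0.02)

  phi_half <- calibrate_weibull_shape(Sigma, beta, snr = 0.25, pilot_size = 2e5, seed = 3)
  expect_lt(abs(phi_half^2 / phi^2 - 0.5), 0.02)

  expect_error(calibrate_weibull_shape(Sigma, rep(0, 4), snr = 0.5), "no signal")
})

test_that("censoring calibration reaches the target rate and respects the admin floor", {
  set.seed(4)
  pilot <- exp(rnorm(5e4, 0, 1.2))
  cal <- calibrate_censoring(0.25, pilot, admin_quantile = 0.90, seed = 9)
  expect_gt(cal$realized_pilot_rate, 0.24)
  expect_lt(cal$realized_pilot_rate, 0.26)
  expect_equal(cal$admin_cutoff, quantile(pilot, 0.9, names = FALSE))

  expect_error(calibrate_censoring(0.05, pilot, admin_quantile = 0.90, seed = 9),
               "administrative censoring alone exceeds")

  # cutoff is stable across pilot seeds
  set.seed(5)
  pilot2 <- exp(rnorm(5e4, 0, 1.2))
  c2 <- calibrate_censoring(0.25, pilot2, admin_quantile = 0.90, seed = 10)
  expect_lt(abs(c2$admin_cutoff - cal$admin_cutoff) / cal$admin_cutoff, 0.05)
})

test_that("simulated datasets are reproducible and match their design", {
  des <- simulation_design(n = 2000, d = 12, rel_var = 0.25, signal_block = 1,
                           exp_var = 0.5, cens_rate = 0.25, seed = 8,
                           pilot_size = 2e4)
  expect_equal(sum(des$influential), 3)
  expect_equal(des$beta[des$influential], make_coefficients(3))
  expect_true(all(des$beta[!des$influential] == 0))

  ds1 <- simulate_dataset(des, seed = 42)
  ds2 <- simulate_dataset(des, seed = 42)
  expect_identical(ds1$sample$times, ds2$sample$times)
  expect_identical(ds1$sample$covariates, ds2$sample$covariates)

  expect_lt(abs(ds1$realized_cens_rate - 0.25), 0.05)

  # empirical covariate correlations track the repaired target
  ds_big <- simulate_dataset(
    simulation_design(n = 5000, d = 12, rel_var = 0.25, signal_block = 1,
                      exp_var = 0.5, cens_rate = 0.25, seed = 8,
                      pilot_size = 2e4), seed = 43)
  emp <- cor(ds_big$sample$covariates)
  gaps <- abs(emp - des$Sigma)
  expect_gt(mean(gaps < 0.05), 0.95)
})

test_that("realized explained variance matches the design (lognormal)", {
  des <- simulation_design(n = 50000, d = 9, rel_var = 1, signal_block = 0,
                           exp_var = 0.5, cens_rate = 0.25,
                           admin_quantile = NULL, seed = 21, pilot_size = 2e4)
  ds <- simulate_dataset(des, seed = 99)
  # regress the (uncensored would be ideal; use all log observed times of
  # events is biased, so recompute T from the linear predictor instead)
  lp <- drop(ds$sample$covariates %*% des$beta)
  # R^2 on the latent log survival times requires the uncensored outcome;
  # reconstruct it by redrawing noise with the same design is not possible
  # here, so check the variance decomposition instead
  v_lp <- var(lp)
  expect_lt(abs(v_lp / (v_lp + des$sigma_eps2) - 0.5), 0.02)
})

test_that("weibull family satisfies the AFT structure", {
  # near-zero censoring so the observed times are effectively the latent T
  des <- simulation_design(n = 30000, d = 6, rel_var = 0.5, signal_block = 0,
                           family = "weibull", snr = 0.5, cens_rate = 0.02,
                           admin_quantile = NULL, seed = 22, pilot_size = 5e4)
  ds <- simulate_dataset(des, seed = 55)
  # conditional mean of log T is linear in the linear predictor with slope 1
  lp <- drop(ds$sample$covariates %*% des$beta)
  ev <- ds$sample$status == 1
  fit <- lm(log(ds$sample$times)[ev] ~ lp[ev])
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  # residual variance matches (pi^2/6)/phi^2
  expect_lt(abs(var(resid(fit)) / ((pi^2 / 6) / des$shape^2) - 1), 0.05)
})
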