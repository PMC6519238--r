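# Synthetic survival studies: multivariate-normal covariates with a
# three-block correlation structure, lognormal or Weibull accelerated
# failure time outcomes with calibrated noise, and lognormal plus
# administrative censoring calibrated to a target rate.

#' Three-block random-sign correlation matrix
#'
#' Builds a d x d correlation matrix with three (near-)equally sized
#' diagonal blocks. Within block b every off-diagonal entry has magnitude
#' \code{block_rhos[b]}; signs are assigned per variable (variable signs s,
#' entry sign s_i * s_j, with the first half of each block positive and the
#' second half negative), so close to half of the within-block correlations
#' are positive and half negative while the block remains an exact
#' sign-flipped equicorrelation matrix (eigenvalues 1 + (k-1) rho and
#' 1 - rho, hence positive definite) and the stated correlation magnitudes
#' survive unchanged. Entries between blocks are zero. Independent
#' per-entry sign draws would instead give a heavily frustrated,
#' far-from-positive-definite matrix whose projection onto the correlation
#' cone destroys the intended magnitudes (for rho = 0.75 the repaired
#' entries collapse to a median magnitude near 0.24). The result is still
#' passed through \code{\link{nearest_correlation}} (a fixed point for this
#' construction) to honor the contract for arbitrary inputs.
#'
#' With the deterministic half/half layout the influential covariates of a
#' scenario (the leading columns of a block) sit in the positively
#' equicorrelated sign group, so a signal block mixes strong positive
#' correlations with effect coefficients of both signs: the antagonistic
#' configuration in which marginal screens are known to break down.
#' \code{scramble_signs = TRUE} randomizes the sign layout (seeded) instead.
#'
#' @param d number of covariates, >= 6. When d is not divisible by 3 the
#'   blocks have sizes ceiling(d/3), ceiling(d/3), d - 2 * ceiling(d/3).
#' @param block_rhos magnitudes of the within-block correlations, length 3;
#'   default c(0.25, 0.5, 0.75).
#' @param seed integer seed; only consulted when \code{scramble_signs}.
#' @param repair if TRUE (default) return the nearest correlation matrix;
#'   if FALSE return the raw block matrix.
#' @param scramble_signs permute the variable signs randomly instead of the
#'   deterministic first-half/second-half layout. Default FALSE.
#' @return correlation matrix with attribute \code{block_sizes}.
#' @export
block_correlation_matrix <- function(d, block_rhos = c(0.25, 0.5, 0.75),
                                     seed = 1L, repair = TRUE,
                                     scramble_signs = FALSE) {
  stopifnot(d >= 6, length(block_rhos) == 3)
  sizes <- block_sizes(d)
  A <- matrix(0, d, d)
  offsets <- cumsum(c(0, sizes[-3]))
  for (b in 1:3) {
    k <- sizes[b]
    idx <- offsets[b] + seq_len(k)
    s <- rep(c(1, -1), c(ceiling(k / 2), floor(k / 2)))
    if (scramble_signs) s <- with_seed(seed + b, sample(s))
    A[idx, idx] <- tcrossprod(s) * block_rhos[b]
  }
  diag(A) <- 1
  out <- if (repair) nearest_correlation(A) else A
  attr(out, "block_sizes") <- sizes
  out
}

block_sizes <- function(d) {
  if (d %% 3 == 0) rep(d / 3, 3)
  else c(ceiling(d / 3), ceiling(d / 3), d - 2 * ceiling(d / 3))
}

#' Nearest correlation matrix
#'
#' Projects a symmetric unit-diagonal matrix onto the set of valid
#' correlation matrices, minimizing the element-wise quadratic distance, via
#' Higham's alternating-projections algorithm (as implemented by
#' \code{Matrix::nearPD} with the correlation constraint).
#'
#' @param A symmetric matrix with unit diagonal.
#' @param tol convergence tolerance on the relative Frobenius change
#'   (default 1e-7).
#' @param max_iter maximum number of iterations (default 200).
#' @return a correlation matrix (unit diagonal, eigenvalues >= -1e-8).
#' @export
nearest_correlation <- function(A, tol = 1e-7, max_iter = 200L) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  if (max(abs(diag(A) - 1)) > 1e-8) stop("A must have unit diagonal")
  res <- Matrix::nearPD(A, corr = TRUE, conv.tol = tol, maxit = max_iter,
                        do2eigen = TRUE)
  if (!res$converged)
    stop("nearest-correlation projection did not converge in ",
         res$iterations, " iterations (normF = ", format(res$normF), ")")
  M <- as.matrix(res$mat)
  dimnames(M) <- NULL
  M
}

#' Equidistant effect coefficients
#'
#' The true effects of the influential covariates: k values equally spaced
#' over [-0.9, 1] (endpoints included). For some k the grid contains an
#' exact zero, i.e. an "influential" covariate with no effect; this is a
#' property of the design and is flagged with a message. The k = 1
#' convention is a single coefficient of 1.
#'
#' @param k number of influential covariates, >= 1.
#' @return numeric vector of length k.
#' @export
make_coefficients <- function(k) {
  stopifnot(k >= 1)
  if (k == 1) return(1)
  beta <- seq(-0.9, 1, length.out = k)
  if (any(abs(beta) < 1e-12))
    message("coefficient grid contains an exact zero: one influential ",
            "covariate carries no effect")
  beta
}

#' Noise variance for a target explained variance (lognormal family)
#'
#' Solves for the Gaussian noise variance of the lognormal AFT model so that
#' the population proportion of Var(log T) explained by the linear predictor
#' equals \code{exp_var}: sigma_eps2 = beta' Sigma beta * (1 - exp_var) /
#' exp_var.
#'
#' @param Sigma covariate covariance matrix.
#' @param beta_full full-length coefficient vector.
#' @param exp_var target explained variance in (0, 1).
#' @return sigma_eps2.
#' @export
calibrate_lognormal_noise <- function(Sigma, beta_full, exp_var) {
  stopifnot(exp_var > 0, exp_var < 1)
  v <- drop(crossprod(beta_full, Sigma %*% beta_full))
  if (v <= 0) stop("beta' Sigma beta is zero: no signal to calibrate against")
  v * (1 - exp_var) / exp_var
}

#' Weibull shape for a target signal-to-noise ratio
#'
#' For Weibull survival T with scale exp(x'beta) and shape phi, log T =
#' x'beta + (1/phi) * log E with E standard exponential, so the residual
#' variance of log T is (pi^2/6)/phi^2. The shape is calibrated by bisection
#' on a pilot draw so that Var(x'beta) / Var(residual) hits \code{snr}
#' within 0.01 relative accuracy. Because the covariates are multivariate
#' normal, the pilot draws the linear predictor directly from
#' N(0, beta' Sigma beta).
#'
#' @param Sigma covariate covariance matrix.
#' @param beta_full full coefficient vector (must carry signal).
#' @param snr target signal-to-noise ratio, > 0; default 0.5.
#' @param pilot_size pilot sample size (default 1e5).
#' @param seed pilot seed.
#' @return shape phi.
#' @export
calibrate_weibull_shape <- function(Sigma, beta_full, snr = 0.5,
                                    pilot_size = 1e5, seed = 1L) {
  stopifnot(snr > 0)
  v <- drop(crossprod(beta_full, Sigma %*% beta_full))
  if (v <= 0) stop("beta' Sigma beta is zero: no signal to calibrate against")
  pilot <- with_seed(seed, list(lp = stats::rnorm(pilot_size, 0, sqrt(v)),
                                loge = log(stats::rexp(pilot_size))))
  v_lp <- stats::var(pilot$lp)
  v_loge <- stats::var(pilot$loge)
  # realized snr(phi) = v_lp / (v_loge / phi^2), increasing in phi
  f <- function(phi) v_lp * phi^2 / v_loge - snr
  lo <- 1e-4; hi <- 1e4
  if (f(lo) > 0 || f(hi) < 0) stop("bisection bracket failure: f(", lo, ") = ",
                                   f(lo), ", f(", hi, ") = ", f(hi))
  mid <- sqrt(lo * hi)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (abs(f(mid)) / snr < 0.002 || (hi - lo) < 1e-12 * hi) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Calibrate the censoring distribution to a target censoring rate
#'
#' The censoring time is lognormal; its log-mean is found by bisection on a
#' pilot draw of the survival process so that the total fraction censored
#' (random censoring plus the administrative cutoff) matches
#' \code{cens_rate} within 0.01. The log-scale defaults to 1.5 times the
#' standard deviation of the pilot log survival times: tying the censoring
#' dispersion to the outcome dispersion (with a factor above 1) keeps the
#' censoring survival function heavier-tailed than the survival process, so
#' the inverse-probability weights downstream have finite variance; a
#' censoring tail lighter than the outcome tail would make the squared
#' weights non-integrable and moment estimates erratic. Administrative
#' censoring truncates follow-up at the \code{admin_quantile} quantile of
#' the marginal distribution of T, estimated once from the pilot and kept
#' fixed.
#'
#' @param cens_rate target overall censoring fraction in (0, 1).
#' @param pilot_T pilot draw of uncensored survival times.
#' @param admin_quantile quantile of T used as administrative cutoff
#'   (default 0.90); \code{NULL} disables administrative censoring.
#' @param seed seed for the pilot censoring draws.
#' @param sdlog log-scale of the censoring lognormal; default
#'   \code{1.5 * sd(log(pilot_T))}.
#' @return list with \code{meanlog}, \code{sdlog}, \code{admin_cutoff}
#'   (Inf when disabled) and \code{realized_pilot_rate}.
#' @export
calibrate_censoring <- function(cens_rate, pilot_T, admin_quantile = 0.90,
                                seed = 1L,
                                sdlog = 1.5 * stats::sd(log(pilot_T))) {
  stopifnot(cens_rate > 0, cens_rate < 1, sdlog > 0)
  if (is.null(admin_quantile) || is.na(admin_quantile)) {
    cutoff <- Inf
  } else {
    stopifnot(admin_quantile > 0, admin_quantile < 1)
    cutoff <- stats::quantile(pilot_T, admin_quantile, names = FALSE)
    admin_floor <- mean(pilot_T > cutoff)
    if (cens_rate < admin_floor - 0.005)
      stop("administrative censoring alone exceeds target: floor ",
           format(admin_floor), " > cens_rate ", cens_rate)
  }
  u <- with_seed(seed, stats::rnorm(length(pilot_T)))
  rate_at <- function(meanlog) {
    C <- exp(meanlog + sdlog * u)
    mean(pilot_T > pmin(C, cutoff))
  }
  lt <- log(pilot_T)
  lo <- min(lt) - 10; hi <- max(lt[is.finite(lt)]) + 10
  # censoring fraction decreases as meanlog grows
  if (rate_at(lo) < cens_rate)
    stop("target censoring rate unreachable: even immediate censoring gives ",
         format(rate_at(lo)))
  r_hi <- rate_at(hi)
  if (r_hi > cens_rate + 0.005) {
    if (!is.finite(cutoff) || r_hi > cens_rate + 0.01)
      stop("target censoring rate below achievable floor ", format(r_hi))
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - cens_rate) < 0.005) break
    if (r > cens_rate) lo <- mid else hi <- mid
  }
  list(meanlog = mid, sdlog = sdlog, admin_cutoff = cutoff,
       realized_pilot_rate = rate_at(mid))
}

#' Specify (and calibrate) a simulation scenario
#'
#' Fixes every ingredient of a synthetic study: the repaired block
#' correlation matrix and its Cholesky factor, the true coefficient vector
#' (the first \code{round(rel_var * d)} covariates of the designated block
#' carry the equidistant effects), the calibrated noise variance (lognormal
#' family) or Weibull shape, and the calibrated censoring distribution with
#' its administrative cutoff. All calibration constants are computed once,
#' from pilot draws of \code{pilot_size} observations, and reused for every
#' dataset drawn from the design.
#'
#' @param n sample size per dataset.
#' @param d number of covariates (>= 6).
#' @param rel_var fraction of influential covariates in (0, 1];
#'   round(rel_var * d) must be >= 1.
#' @param block_rhos within-block correlation magnitudes (default
#'   c(0.25, 0.5, 0.75)).
#' @param signal_block which block (1, 2 or 3) hosts the influential
#'   covariates; default 1.
#' @param family "lognormal" or "weibull".
#' @param exp_var target explained variance of log T (lognormal family);
#'   default 0.5.
#' @param snr target signal-to-noise ratio (weibull family); default 0.5.
#' @param cens_rate target overall censoring fraction; default 0.25.
#' @param admin_quantile administrative-censoring quantile of T (default
#'   0.90); \code{NULL} disables the administrative cutoff.
#' @param seed base seed; drives the correlation signs, the pilot draws and
#'   the default dataset seed.
#' @param pilot_size pilot sample size for the calibration draws
#'   (default 1e5).
#' @return object of class \code{simulation_design}.
#' @export
simulation_design <- function(n, d, rel_var, block_rhos = c(0.25, 0.5, 0.75),
                              signal_block = 1L, family = c("lognormal", "weibull"),
                              exp_var = 0.5, snr = 0.5, cens_rate = 0.25,
                              admin_quantile = 0.90, seed = 1L,
                              pilot_size = 1e5) {
  family <- match.arg(family)
  stopifnot(n >= 2, d >= 6, rel_var > 0, rel_var <= 1,
            signal_block %in% 0:3)
  k <- round(rel_var * d)
  if (k < 1) stop("rel_var * d must round to at least 1 influential covariate")

  sub_seeds <- derive_seeds(seed, 3L)
  Sigma <- block_correlation_matrix(d, block_rhos, seed = sub_seeds[1])
  sizes <- attr(Sigma, "block_sizes")
  offsets <- cumsum(c(0, sizes[-3]))
  # signal_block 0: influential set spans the whole covariate vector (used
  # e.g. for parameter-recovery analyses); 1..3: first k columns of a block
  if (signal_block == 0) {
    if (k > d) stop("rel_var * d exceeds d")
    first_idx <- 1L
  } else {
    if (k > sizes[signal_block])
      stop("rel_var * d = ", k, " exceeds the size of block ", signal_block)
    first_idx <- offsets[signal_block] + 1L
  }
  influential <- rep(FALSE, d)
  influential[first_idx + seq_len(k) - 1L] <- TRUE
  beta <- numeric(d)
  beta[influential] <- make_coefficients(k)

  chol_upper <- chol(Sigma)

  if (family == "lognormal") {
    sigma_eps2 <- calibrate_lognormal_noise(Sigma, beta, exp_var)
    shape <- NA_real_
  } else {
    shape <- calibrate_weibull_shape(Sigma, beta, snr = snr,
                                     pilot_size = pilot_size,
                                     seed = sub_seeds[2])
    sigma_eps2 <- NA_real_
  }

  v <- drop(crossprod(beta, Sigma %*% beta))
  pilot <- with_seed(sub_seeds[2], {
    lp <- stats::rnorm(pilot_size, 0, sqrt(v))
    if (family == "lognormal") exp(lp + stats::rnorm(pilot_size, 0, sqrt(sigma_eps2)))
    else exp(lp) * stats::rexp(pilot_size)^(1 / shape)
  })
  cens <- calibrate_censoring(cens_rate, pilot, admin_quantile,
                              seed = sub_seeds[3])

  structure(list(
    n = n, d = d, rel_var = rel_var, k = k, block_rhos = block_rhos,
    signal_block = signal_block, family = family, exp_var = exp_var,
    snr = snr, cens_rate = cens_rate, admin_quantile = admin_quantile,
    seed = seed, pilot_size = pilot_size,
    Sigma = Sigma, chol_upper = chol_upper, beta = beta,
    influential = influential, sigma_eps2 = sigma_eps2, shape = shape,
    censoring = cens
  ), class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("<simulation_design> n = %d, d = %d, %d influential (block %d), %s family\n",
              x$n, x$d, x$k, x$signal_block, x$family))
  cat(sprintf("target censoring %.2f (admin cutoff %s), seed %d\n",
              x$cens_rate,
              if (is.finite(x$censoring$admin_cutoff))
                format(x$censoring$admin_cutoff, digits = 4) else "none",
              x$seed))
  invisible(x)
}

#' Draw one dataset from a simulation design
#'
#' Generates covariates from the repaired block-correlated multivariate
#' normal, survival times from the designed AFT family, censoring times from
#' the calibrated lognormal distribution truncated by the administrative
#' cutoff, and returns the observed (censored) sample together with the
#' ground truth. Fully reproducible from the seed.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param seed dataset seed; defaults to the design seed.
#' @return object of class \code{simulated_dataset}: list with \code{sample}
#'   (a \code{\link{survival_sample}}), \code{beta_true},
#'   \code{influential_mask}, \code{realized_cens_rate} and \code{design}.
#' @export
simulate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n; d <- design$d
  dat <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * d), n, d)
    X <- Z %*% design$chol_upper
    lp <- drop(X %*% design$beta)
    T <- if (design$family == "lognormal") {
      exp(lp + stats::rnorm(n, 0, sqrt(design$sigma_eps2)))
    } else {
      exp(lp) * stats::rexp(n)^(1 / design$shape)
    }
    C <- pmin(stats::rlnorm(n, design$censoring$meanlog, design$censoring$sdlog),
              design$censoring$admin_cutoff)
    list(X = X, T = T, C = C)
  })
  obs <- pmin(dat$T, dat$C)
  status <- as.numeric(dat$T <= dat$C)
  realized <- mean(status == 0)
  if (n >= 500 && abs(realized - design$cens_rate) > 0.05)
    message("realized censoring rate ", format(realized, digits = 3),
            " deviates from target ", design$cens_rate)
  colnames(dat$X) <- paste0("X", seq_len(d))
  structure(list(
    sample = survival_sample(obs, status, dat$X),
    beta_true = design$beta,
    influential_mask = design$influential,
    realized_cens_rate = realized,
    design = design
  ), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> n = %d, d = %d, realized censoring %.3f\n",
              x$sample$n, x$sample$d, x$realized_cens_rate))
  invisible(x)
}
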