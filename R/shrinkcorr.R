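#' Standardize the columns of a covariate matrix
#'
#' Centers every column at its sample mean and scales it by its sample
#' standard deviation (n - 1 divisor). Constant columns make correlations
#' undefined and are rejected with an error naming the offending covariates.
#'
#' @param X numeric matrix, n x d, n >= 2.
#' @return list with \code{Xs} (standardized matrix), \code{means} and
#'   \code{sds} (length-d vectors).
#' @export
standardize_columns <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to standardize")
  means <- colMeans(X)
  Xc <- sweep(X, 2L, means, "-")
  sds <- sqrt(colSums(Xc^2) / (n - 1))
  const <- sds <= .Machine$double.eps * 10 * pmax(abs(means), 1)
  if (any(const)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("X", seq_len(ncol(X)))
    stop("constant column(s) cannot be standardized: ",
         paste(nm[const], collapse = ", "))
  }
  Xs <- sweep(Xc, 2L, sds, "/")
  list(Xs = Xs, means = means, sds = sds)
}

#' Shrinkage intensity for the correlation matrix
#'
#' Estimates the mixing weight lambda of the shrinkage correlation estimator
#' R_shrink = lambda * I + (1 - lambda) * R_X as the ratio of the summed
#' estimated variances of the off-diagonal sample correlations to their
#' summed squares, clamped into [0, 1]. Large lambda means the empirical
#' correlations are noise-dominated and the estimate is pulled toward the
#' identity.
#'
#' @param Xs standardized matrix from \code{\link{standardize_columns}}.
#' @return lambda in [0, 1].
#'
#' @details The variance of a sample correlation r_jk is estimated by
#'   n / (n-1)^3 * sum_i (w_ijk - mean(w_jk))^2 with w_ijk the product of the
#'   i-th standardized entries of columns j and k, the unbiased estimator of
#'   Schaefer-Strimmer type shrinkage. All pair sums are accumulated through
#'   row sums and the singular values of Xs, so no d x d matrix is formed.
#'   With fewer than two columns, or when all off-diagonal correlations
#'   vanish, lambda is defined as 1 (pure identity target).
#' @export
shrinkage_intensity <- function(Xs) {
  n <- nrow(Xs)
  d <- ncol(Xs)
  if (d < 2L) return(1)
  if (n < 3L) stop("need n >= 3 to estimate correlation variances")

  # sum over ordered pairs (j,k), j != k, of sum_i w_ijk^2 and of wbar_jk^2
  rs2 <- rowSums(Xs^2)
  sum_w2_all <- sum(rs2^2)          # includes j == k terms
  sum_w2_diag <- sum(Xs^4)
  sv <- svd(Xs, nu = 0, nv = 0)$d
  sum_wbar2_all <- sum(sv^4) / n^2  # ||Xs'Xs/n||_F^2
  sum_wbar2_diag <- d * ((n - 1) / n)^2  # standardized columns: sum x_ij^2 = n-1

  ss_w <- (sum_w2_all - sum_w2_diag) - n * (sum_wbar2_all - sum_wbar2_diag)
  var_sum <- n / (n - 1)^3 * ss_w
  # r_jk = n/(n-1) * wbar_jk
  r2_sum <- (n / (n - 1))^2 * (sum_wbar2_all - sum_wbar2_diag)
  if (r2_sum <= .Machine$double.eps) return(1)
  min(1, max(0, var_sum / r2_sum))
}

#' Build the shrinkage-correlation operator
#'
#' Represents R_shrink = lambda * I + (1 - lambda) * R_X through the non-null
#' eigenpairs of the sample correlation matrix R_X, obtained from the
#' singular value decomposition of the standardized data, so that the inverse
#' square root can later be applied to vectors without ever materializing a
#' d x d matrix. For modest d (<= 64) a dense symmetric eigendecomposition
#' of R_X is used instead; both paths represent the same operator.
#'
#' @param Xs standardized matrix, n x d.
#' @param lambda_hat shrinkage intensity in [0, 1], typically from
#'   \code{\link{shrinkage_intensity}}.
#' @param dense_limit dimension at or below which the dense eigen path is
#'   taken. Default 64.
#' @return an object of class \code{shrink_op} with fields \code{lambda_hat},
#'   \code{left_vectors} (d x m orthonormal), \code{eigenvalues} (length m,
#'   eigenvalues of R_X on its column space), \code{d}.
#' @export
build_shrink_op <- function(Xs, lambda_hat, dense_limit = 64L) {
  if (!is.matrix(Xs)) Xs <- as.matrix(Xs)
  n <- nrow(Xs)
  d <- ncol(Xs)
  stopifnot(length(lambda_hat) == 1L, lambda_hat >= 0, lambda_hat <= 1)

  if (d <= dense_limit) {
    R <- crossprod(Xs) / (n - 1)
    e <- eigen(R, symmetric = TRUE)
    mu <- pmax(e$values, 0)
    U <- e$vectors
  } else {
    sv <- svd(Xs / sqrt(n - 1), nu = 0)
    mu <- sv$d^2
    keep <- mu > max(mu[1], 1) * d * .Machine$double.eps
    mu <- mu[keep]
    U <- sv$v[, keep, drop = FALSE]
  }

  m <- length(mu)
  rank_tol <- max(mu[1], 1) * d * .Machine$double.eps
  full_rank <- m == d && all(mu > rank_tol)
  if (lambda_hat == 0 && !full_rank)
    stop("R_shrink singular; lambda must be > 0 when d exceeds the rank of R_X")

  structure(list(lambda_hat = lambda_hat, left_vectors = U, eigenvalues = mu,
                 d = d, full_rank = full_rank),
            class = "shrink_op")
}

#' Apply the inverse square root of the shrinkage correlation matrix
#'
#' Computes R_shrink^{-1/2} V for a d x k matrix (or length-d vector) V
#' using the stored eigenpairs: on the column space of R_X the eigenvalues
#' lambda + (1 - lambda) * mu_j are used, on its orthogonal complement
#' R_shrink acts as lambda * I. Cost O(d * m * k); no d x d matrix is formed.
#'
#' @param op a \code{shrink_op} from \code{\link{build_shrink_op}}.
#' @param V numeric vector of length d or matrix d x k.
#' @return matrix d x k (or vector if V was a vector).
#' @export
apply_inv_sqrt <- function(op, V) {
  stopifnot(inherits(op, "shrink_op"))
  was_vec <- is.null(dim(V))
  if (was_vec) V <- matrix(V, ncol = 1L)
  if (nrow(V) != op$d) stop("dimension mismatch: V must have ", op$d, " rows")

  lam <- op$lambda_hat
  if (lam == 1) {
    out <- V
  } else {
    inv_sqrt_eig <- 1 / sqrt(lam + (1 - lam) * op$eigenvalues)
    U <- op$left_vectors
    UtV <- crossprod(U, V)
    if (op$full_rank) {
      out <- U %*% (inv_sqrt_eig * UtV)
    } else {
      # lam > 0 guaranteed at build time when rank-deficient
      out <- V / sqrt(lam) + U %*% ((inv_sqrt_eig - 1 / sqrt(lam)) * UtV)
    }
  }
  if (was_vec) drop(out) else out
}
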