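#' Construct a right-censored survival sample
#'
#' Bundles observed follow-up times, event indicators and a covariate matrix
#' into a validated container used throughout the package. Observed times are
#' the minimum of the true event time and the censoring time; the status
#' indicator is 1 when the event was observed and 0 when the observation was
#' censored.
#'
#' @param times numeric vector of strictly positive observed times, length n.
#' @param status integer/numeric vector of 0/1 event indicators, length n
#'   (1 = event observed, 0 = right-censored).
#' @param covariates numeric matrix with n rows and one column per covariate.
#'   A data frame of numeric columns is accepted and coerced.
#' @param covariate_names optional character vector of covariate names;
#'   defaults to existing column names or \code{X1..Xd}.
#'
#' @return An object of class \code{survival_sample}: a list with elements
#'   \code{times}, \code{status}, \code{covariates} (matrix with column
#'   names), \code{n} and \code{d}.
#'
#' @details Missing values anywhere in the inputs are rejected: pairwise
#'   moments and correlations are undefined under missingness, and imputation
#'   is deliberately out of scope. Log-transformed times are computed on
#'   demand by downstream estimators, which is why times must be positive.
#'
#' @examples
#' s <- survival_sample(times = c(2, 5, 1), status = c(1, 0, 1),
#'                      covariates = cbind(a = c(1, 2, 3), b = c(0, 1, 0)))
#' s$d
#' @export
survival_sample <- function(times, status, covariates, covariate_names = NULL) {
  times <- as.numeric(times)
  status <- as.numeric(status)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, nrow = length(times))
  storage.mode(covariates) <- "double"

  n <- length(times)
  if (n < 2L) stop("need at least 2 observations, got ", n)
  if (length(status) != n) stop("length(status) != length(times)")
  if (nrow(covariates) != n) stop("nrow(covariates) != length(times)")
  if (anyNA(times) || anyNA(status) || anyNA(covariates))
    stop("missing values are not allowed in times, status or covariates")
  if (any(times <= 0)) {
    bad <- which(times <= 0)
    stop("times must be strictly positive; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(status %in% c(0, 1))) {
    bad <- which(!(status %in% c(0, 1)))
    stop("status must be 0 or 1; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }

  d <- ncol(covariates)
  if (is.null(covariate_names)) {
    covariate_names <- colnames(covariates)
    if (is.null(covariate_names)) covariate_names <- paste0("X", seq_len(d))
  }
  if (length(covariate_names) != d) stop("covariate_names must have length d = ", d)
  colnames(covariates) <- covariate_names

  structure(
    list(times = times, status = status, covariates = covariates, n = n, d = d),
    class = "survival_sample"
  )
}

#' @export
print.survival_sample <- function(x, ...) {
  cat("<survival_sample> n =", x$n, ", d =", x$d,
      sprintf(", events = %d (%.1f%% censored)\n",
              sum(x$status == 1), 100 * mean(x$status == 0)))
  invisible(x)
}

is_survival_sample <- function(x) inherits(x, "survival_sample")

assert_sample <- function(sample) {
  if (!is_survival_sample(sample)) stop("expected a 'survival_sample' object")
  invisible(sample)
}
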