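#' Kaplan-Meier estimate of the censoring survival function
#'
#' Estimates G(t) = P(C > t), the survival function of the censoring process,
#' by the product-limit estimator applied with the flipped event indicator
#' (censorings are the "events"). This is the reverse Kaplan-Meier estimator
#' that underlies inverse-probability-of-censoring (IPC) weighting.
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param floor_nu small positive lower bound for evaluated survival values;
#'   mirrors the positivity assumption G(.) > nu > 0 required for IPC
#'   weighting. Default \code{1e-8}.
#'
#' @return An object of class \code{censoring_curve}: list with
#'   \code{jump_times} (times at which at least one censoring occurred),
#'   \code{surv_values} (right-continuous step values after each jump),
#'   and \code{floor_nu}.
#'
#' @details At tied observation times, events are taken to precede
#'   censorings (the standard convention): the risk set for a censoring at
#'   time t excludes observations whose event occurred at t. Because the
#'   logarithm is strictly monotone, the estimate computed on the raw time
#'   scale and evaluated at raw times is identical to the log-scale
#'   formulation; the raw scale is used here.
#'
#' @seealso \code{\link{ipc_weights}}
#' @export
censoring_survival <- function(sample, floor_nu = 1e-8) {
  assert_sample(sample)
  if (all(sample$status == 0)) stop("no events: all observations are censored")
  stopifnot(is.numeric(floor_nu), length(floor_nu) == 1L, floor_nu > 0)

  tt <- sample$times
  cens <- sample$status == 0
  ut <- sort(unique(tt[cens]))
  if (length(ut) == 0L) {
    return(structure(list(jump_times = numeric(0), surv_values = numeric(0),
                          floor_nu = floor_nu),
                     class = "censoring_curve"))
  }
  # risk set for a censoring at time u: still under observation just before u,
  # minus events tied at u (events precede censorings)
  n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
  n_event_tied <- vapply(ut, function(u) sum(tt == u & !cens), numeric(1))
  n_cens <- vapply(ut, function(u) sum(tt == u & cens), numeric(1))
  at_risk <- n_risk - n_event_tied
  surv <- cumprod(1 - n_cens / at_risk)

  structure(list(jump_times = ut, surv_values = surv, floor_nu = floor_nu),
            class = "censoring_curve")
}

#' Evaluate a censoring survival curve
#'
#' @param curve a \code{censoring_curve} from \code{\link{censoring_survival}}.
#' @param t numeric vector of evaluation times.
#' @param left if \code{TRUE} (default) return the left limit G(t-), i.e. the
#'   value just before \code{t}; otherwise the right-continuous value G(t).
#' @return numeric vector of survival probabilities, floored at
#'   \code{curve$floor_nu}.
#' @export
eval_censoring <- function(curve, t, left = TRUE) {
  stopifnot(inherits(curve, "censoring_curve"))
  if (length(curve$jump_times) == 0L) return(rep(1, length(t)))
  # number of jumps strictly before t (left limit) or at-or-before t
  idx <- findInterval(t, curve$jump_times, left.open = left)
  vals <- c(1, curve$surv_values)[idx + 1L]
  pmax(vals, curve$floor_nu)
}

#' Inverse-probability-of-censoring weights
#'
#' Computes the IPC weight of each observation: w_i = Delta_i / G(T_i-),
#' where G is the estimated censoring survival function evaluated at the
#' left limit of the observed time. Censored observations receive weight
#' exactly zero; event observations are up-weighted by the inverse
#' probability of having remained uncensored.
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param curve a \code{censoring_curve} built from the same sample
#'   (defaults to \code{censoring_survival(sample)}), or a numeric vector of
#'   length n with externally supplied per-observation censoring-survival
#'   evaluations (an injection point for covariate-conditional censoring
#'   models, which this package does not itself fit).
#' @return numeric vector of non-negative weights, length n. In the absence
#'   of censoring every weight is exactly 1.
#' @examples
#' s <- survival_sample(c(1, 2, 3), c(1, 0, 1), matrix(rnorm(3)))
#' ipc_weights(s)  # 1, 0, 2
#' @export
ipc_weights <- function(sample, curve = censoring_survival(sample)) {
  assert_sample(sample)
  if (is.numeric(curve)) {
    if (length(curve) != sample$n) stop("supplied G evaluations must have length n")
    if (any(curve <= 0)) stop("supplied G evaluations must be positive")
    g <- curve
  } else {
    g <- eval_censoring(curve, sample$times, left = TRUE)
  }
  w <- sample$status / g
  w[sample$status == 0] <- 0
  w
}
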