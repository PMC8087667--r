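#' Negative-binomial log probability mass
#'
#' Mean/inverse-dispersion parametrization: `NB(mu, theta)` has mean `mu`
#' and variance `mu + mu^2 / theta`; smaller `theta` means more
#' between-cell heterogeneity. Computed via log-gamma so non-integer
#' `theta` is exact.
#'
#' @param v Non-negative integer vector of counts.
#' @param mu Positive mean (scalar or vector recycled against `v`).
#' @param theta Positive inverse dispersion (scalar or vector).
#' @return Numeric vector of log-probabilities, one per element of `v`.
#' @export
nb_logpmf <- function(v, mu, theta) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  if (any(v < 0 | v != round(v))) {
    stop("v must contain non-negative integers", call. = FALSE)
  }
  lgamma(v + theta) - lgamma(v + 1) - lgamma(theta) +
    theta * log(theta / (theta + mu)) + v * log(mu / (theta + mu))
}

#' Draw negative-binomial counts
#'
#' Two sampling routes: directly through the NB quantile machinery, or as
#' the gamma-Poisson mixture (gamma with shape `theta` and mean `mu`, used
#' as a Poisson rate). The two agree in distribution; both are exposed so
#' the equivalence can be checked.
#'
#' @param n Number of draws.
#' @inheritParams nb_logpmf
#' @param method `"nb"` (direct) or `"gamma_poisson"` (mixture route).
#' @return Integer vector of length `n`.
#' @export
rnb <- function(n, mu, theta, method = c("nb", "gamma_poisson")) {
  method <- match.arg(method)
  if (method == "nb") {
    stats::rnbinom(n, size = theta, mu = mu)
  } else {
    rate <- stats::rgamma(n, shape = theta, scale = mu / theta)
    stats::rpois(n, rate)
  }
}

#' Score function of the NB log-likelihood in theta
#'
#' First derivative with respect to the inverse dispersion of the summed
#' log-likelihood of counts `x` with per-observation means `mu`:
#' `sum(digamma(x + theta) - digamma(theta) + log(theta/(theta + mu)) + 1 -
#' (x + theta)/(theta + mu))`.
#'
#' @param theta Positive scalar.
#' @param x Non-negative integer vector of counts for one gene.
#' @param mu Positive means, scalar or one per observation.
#' @return The scalar score `V(theta)`.
#' @export
nb_score <- function(theta, x, mu) {
  stopifnot(theta > 0, all(mu > 0), all(x >= 0))
  sum(digamma(x + theta) - digamma(theta) + log(theta / (theta + mu)) +
        1 - (x + theta) / (theta + mu))
}

#' Observed Fisher information of the NB log-likelihood in theta
#'
#' Negative second derivative of the summed log-likelihood; additive over
#' independent observations and positive at an interior optimum.
#'
#' @inheritParams nb_score
#' @return The scalar observed information `I(theta)`.
#' @export
nb_fisher_info <- function(theta, x, mu) {
  stopifnot(theta > 0, all(mu > 0), all(x >= 0))
  d2 <- sum(trigamma(x + theta) - trigamma(theta) + 1 / theta -
              1 / (theta + mu) - (mu - x) / (theta + mu)^2)
  out <- -d2
  if (!is.finite(out)) stop("non-finite Fisher information", call. = FALSE)
  out
}

#' Configuration for regularized Fisher scoring
#'
#' @param lambda_reg Non-negative regularization strength `lambda`; the
#'   penalty enters the update as `+ 2*lambda/theta^3` in the numerator and
#'   `+ 6*lambda/theta^4` in the denominator, so small `theta` is pushed
#'   upward (strongest regularization where estimated heterogeneity is
#'   largest).
#' @param max_iter Maximum scoring iterations.
#' @param tol Convergence tolerance on the relative change in `theta`.
#' @param theta_bounds Lower/upper clip for the estimate.
#' @return A list of class `"fisher_scoring_config"`.
#' @export
fisher_scoring_config <- function(lambda_reg = 5, max_iter = 100L,
                                  tol = 1e-8, theta_bounds = c(0.01, 1000)) {
  stopifnot(lambda_reg >= 0, tol > 0, theta_bounds[1] > 0,
            theta_bounds[1] < theta_bounds[2])
  structure(list(lambda_reg = lambda_reg, max_iter = as.integer(max_iter),
                 tol = tol, theta_bounds = theta_bounds),
            class = "fisher_scoring_config")
}

#' One regularized Fisher-scoring update of theta
#'
#' `theta_new = theta + (V(theta) + 2*lambda/theta^3) /
#' (I(theta) + 6*lambda/theta^4)`, clipped into `theta_bounds`. If the
#' penalized information is not positive the step direction is kept but its
#' magnitude is halved against the absolute denominator, with a warning.
#'
#' @param theta_k Current positive iterate.
#' @inheritParams nb_score
#' @param lambda_reg Non-negative regularization strength.
#' @param theta_bounds Clip range for the updated value.
#' @return Updated `theta`.
#' @export
fisher_scoring_update <- function(theta_k, x, mu, lambda_reg = 0,
                                  theta_bounds = c(0.01, 1000)) {
  stopifnot(theta_k > 0)
  num <- nb_score(theta_k, x, mu) + lambda_reg * 2 / theta_k^3
  den <- nb_fisher_info(theta_k, x, mu) + lambda_reg * 6 / theta_k^4
  if (den <= 0) {
    warning("non-positive penalized information at theta = ", theta_k,
            "; halving the step", call. = FALSE)
    step <- num / (abs(den) + .Machine$double.eps) / 2
  } else {
    step <- num / den
  }
  min(max(theta_k + step, theta_bounds[1]), theta_bounds[2])
}

# method-of-moments start: theta = mean^2 / (var - mean), clipped
theta_mom <- function(x, bounds = c(0.01, 1000)) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= m || m == 0) return(bounds[2])
  min(max(m^2 / (v - m), bounds[1]), bounds[2])
}

#' Estimate per-gene inverse dispersion by regularized Fisher scoring
#'
#' Iterates [fisher_scoring_update()] from a method-of-moments start until
#' the relative change in `theta` drops below `cfg$tol` or `cfg$max_iter`
#' is reached. All-zero genes cannot identify `theta` and return the upper
#' bound with a warning.
#'
#' @param x Non-negative integer counts of one gene across cells.
#' @param mu Positive means, scalar or one per cell.
#' @param cfg A [fisher_scoring_config()].
#' @return The estimate, a positive scalar with attributes `converged`
#'   (logical) and `iterations` (integer).
#' @export
estimate_theta <- function(x, mu, cfg = fisher_scoring_config()) {
  if (!length(x)) stop("x must be nonempty", call. = FALSE)
  bounds <- cfg$theta_bounds
  if (all(x == 0)) {
    warning("all-zero gene: theta set to upper bound ", bounds[2],
            call. = FALSE)
    return(structure(bounds[2], converged = FALSE, iterations = 0L))
  }
  theta <- theta_mom(x, bounds)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    theta_new <- fisher_scoring_update(theta, x, mu, cfg$lambda_reg, bounds)
    delta <- abs(theta_new - theta) / theta
    theta <- theta_new
    if (delta < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Fisher scoring did not converge in ", cfg$max_iter,
            " iterations (last relative change above tol)", call. = FALSE)
  }
  structure(theta, converged = converged, iterations = it)
}
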