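#' Gibbs-sampler exactness check on a truncated state space
#'
#' Validation utility for the scDBM conditional samplers: on a tiny model
#' whose visible counts are truncated to `0..x_max`, the full joint over
#' `(x, h1, h2)` can be enumerated and the Boltzmann distribution
#' `exp(-E)/Z` computed exactly. Long Gibbs runs using the model's
#' conditionals (with the visible conditional renormalized over the
#' truncated support) must reproduce it; the total-variation distance
#' between the empirical and exact distributions is returned. Consistency
#' here exercises the energy, all three conditionals, and their mutual
#' compatibility (detailed balance).
#'
#' @param p An [scdbm_params()] object with a small state space
#'   (`M * log(x_max) + K + L` must keep `(x_max+1)^M * 2^(K+L)`
#'   enumerable).
#' @param x_max Truncation bound for the visible counts.
#' @param n_chains Parallel Gibbs chains.
#' @param sweeps Post-burn-in sweeps to tally (every sweep of every chain
#'   contributes one sample).
#' @param burn_in Discarded initial sweeps.
#' @param seed Integer seed.
#' @return The total-variation distance, with attribute `n_samples`.
#' @export
scdbm_gibbs_tv <- function(p, x_max = 10L, n_chains = 2000L,
                           sweeps = 1500L, burn_in = 300L, seed = 1L) {
  M <- length(p$a); K <- length(p$b1); L <- length(p$b2)
  n_x <- (x_max + 1L)^M
  n_states <- n_x * 2^(K + L)
  if (n_states > 1e6) stop("state space too large to enumerate",
                           call. = FALSE)
  vals <- 0:x_max

  # exact Boltzmann distribution on the truncated space
  Xg <- as.matrix(expand.grid(rep(list(vals), M)))
  H1g <- binary_configs(K)
  H2g <- binary_configs(L)
  lbin <- matrix(0, nrow(Xg), M)
  for (m in seq_len(M)) {
    lbin[, m] <- lgamma(Xg[, m] + p$theta[m]) - lgamma(p$theta[m]) -
      lgamma(Xg[, m] + 1)
  }
  # -E = a'x + sum lbin + b1'h1 + b2'h2 + x'W1h1 + h1'W2h2
  negE_x <- drop(Xg %*% p$a) + rowSums(lbin)            # n_x
  negE_x_h1 <- Xg %*% p$W1                              # n_x x K -> via H1
  negE_h1 <- drop(H1g %*% p$b1)
  negE_h2 <- drop(H2g %*% p$b2)
  cross12 <- H1g %*% p$W2 %*% t(H2g)                    # 2^K x 2^L
  logp <- array(0, c(n_x, 2^K, 2^L))
  xh1 <- negE_x_h1 %*% t(H1g)                           # n_x x 2^K
  for (i in seq_len(2^K)) {
    logp[, i, ] <- outer(negE_x + xh1[, i] + negE_h1[i],
                         negE_h2 + cross12[i, ], "+")
  }
  logp <- logp - max(logp)
  p_exact <- exp(logp)
  p_exact <- p_exact / sum(p_exact)

  # Gibbs with the truncated visible conditional
  counts <- withr::with_seed(seed, {
    Xc <- matrix(sample(vals, n_chains * M, replace = TRUE), n_chains)
    H2c <- matrix(as.integer(stats::runif(n_chains * L) < 0.5), n_chains)
    tally <- numeric(n_states)
    for (s in seq_len(burn_in + sweeps)) {
      P1 <- stats::plogis(hidden1_activation(Xc, H2c, p))
      H1c <- matrix(as.integer(stats::runif(length(P1)) < P1), n_chains)
      P2 <- stats::plogis(hidden2_activation(H1c, p))
      H2c <- matrix(as.integer(stats::runif(length(P2)) < P2), n_chains)
      Ahat <- visible_natural(H1c, p)
      for (m in seq_len(M)) {
        lp <- outer(Ahat[, m], vals) +
          matrix(lgamma(vals + p$theta[m]) - lgamma(p$theta[m]) -
                   lgamma(vals + 1), n_chains, x_max + 1, byrow = TRUE)
        lp <- lp - apply(lp, 1, max)
        w <- exp(lp)
        cw <- w %*% upper.tri(diag(x_max + 1), diag = TRUE)
        u <- stats::runif(n_chains) * cw[, x_max + 1]
        Xc[, m] <- rowSums(u > cw)
      }
      if (s > burn_in) {
        state <- Xc[, 1]
        mult <- x_max + 1L
        for (m in seq_len(M)[-1]) {
          state <- state + Xc[, m] * mult
          mult <- mult * (x_max + 1L)
        }
        for (k in seq_len(K)) {
          state <- state + H1c[, k] * mult
          mult <- mult * 2L
        }
        for (l in seq_len(L)) {
          state <- state + H2c[, l] * mult
          mult <- mult * 2L
        }
        tt <- tabulate(state + 1L, nbins = n_states)
        tally <- tally + tt
      }
    }
    tally
  })
  emp <- counts / sum(counts)
  tv <- 0.5 * sum(abs(emp - as.vector(p_exact)))
  structure(tv, n_samples = sum(counts))
}
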