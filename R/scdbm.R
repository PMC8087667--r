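#' Parameters of the negative-binomial deep Boltzmann machine
#'
#' A three-layer Boltzmann machine whose visible layer models UMI counts
#' for `M` genes with negative-binomial units (an exponential-family
#' harmonium) and whose two hidden layers are binary. The energy of a state
#' `(x, h1, h2)` is
#' `E = -a'x - sum_m log((x_m + theta_m - 1)! / ((theta_m - 1)! x_m!))
#'  - b1'h1 - b2'h2 - x'W1 h1 - h1'W2 h2`.
#' Because the visible bias `a` acts on the natural-parameter (log) scale,
#' validity of the model requires `a <= -eps` elementwise and `W1 <= 0`,
#' which together keep the per-gene natural parameter negative for every
#' hidden configuration.
#'
#' @param a Visible bias, length `M`, all entries `<= -eps`.
#' @param b1,b2 Hidden biases, lengths `K` and `L`.
#' @param W1 `M x K` visible-to-hidden weights, all entries `<= 0`.
#' @param W2 `K x L` hidden-to-hidden weights (unconstrained).
#' @param theta Per-gene inverse dispersion, positive, length `M`.
#' @param eps Feasibility margin for `a` (default `1e-10`).
#' @return A list of class `"scdbm_params"`.
#' @export
scdbm_params <- function(a, b1, b2, W1, W2, theta, eps = 1e-10) {
  a <- as.numeric(a); b1 <- as.numeric(b1); b2 <- as.numeric(b2)
  W1 <- as.matrix(W1); W2 <- as.matrix(W2); theta <- as.numeric(theta)
  M <- length(a); K <- length(b1); L <- length(b2)
  if (!identical(dim(W1), c(M, K))) stop("W1 must be M x K", call. = FALSE)
  if (!identical(dim(W2), c(K, L))) stop("W2 must be K x L", call. = FALSE)
  if (length(theta) != M) stop("theta must have length M", call. = FALSE)
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  if (any(a > -eps)) stop("visible bias must satisfy a <= -eps", call. = FALSE)
  if (any(W1 > 0)) stop("W1 entries must be <= 0", call. = FALSE)
  structure(list(a = a, b1 = b1, b2 = b2, W1 = W1, W2 = W2, theta = theta,
                 eps = eps),
            class = "scdbm_params")
}

#' Clip parameters back into the feasible region
#'
#' Applies `a_m <- min(a_m, -eps)` and `W1 <- pmin(W1, 0)`; all other
#' fields are untouched. Idempotent; applied after every gradient step
#' during training.
#'
#' @param p A parameter list (fields as in [scdbm_params()]).
#' @param eps Feasibility margin.
#' @return The clipped parameter list.
#' @export
apply_constraints <- function(p, eps = 1e-10) {
  p$a <- pmin(p$a, -eps)
  p$W1 <- pmin(p$W1, 0)
  p
}

#' Energy of a joint state
#'
#' @param x Non-negative integer vector (length `M`).
#' @param h1,h2 Binary vectors (lengths `K`, `L`).
#' @param p An [scdbm_params()] object.
#' @return The scalar energy; lower-energy states are more probable.
#' @export
scdbm_energy <- function(x, h1, h2, p) {
  if (length(x) != length(p$a) || length(h1) != length(p$b1) ||
      length(h2) != length(p$b2)) {
    stop("state dimensions do not match parameters", call. = FALSE)
  }
  lbinom <- lgamma(x + p$theta) - lgamma(p$theta) - lgamma(x + 1)
  -sum(p$a * x) - sum(lbinom) - sum(p$b1 * h1) - sum(p$b2 * h2) -
    drop(x %*% p$W1 %*% h1) - drop(h1 %*% p$W2 %*% h2)
}

# natural parameter of the visible units given h1 (rows = states)
visible_natural <- function(H1, p) {
  sweep(H1 %*% t(p$W1), 2, p$a, "+")
}

#' Conditional distribution of the visible layer given h1
#'
#' Each gene is conditionally negative binomial with natural parameter
#' `a_hat_m = a_m + sum_k W1_mk h1_k` and mean
#' `mu_hat_m = theta_m * exp(a_hat_m) / (1 - exp(a_hat_m))`.
#'
#' @param h1 Binary vector of first-hidden-layer states.
#' @param p An [scdbm_params()] object.
#' @return A list with elements `mu` and `theta` (per-gene vectors).
#' @export
visible_conditional <- function(h1, p) {
  ahat <- drop(visible_natural(matrix(h1, 1), p))
  if (any(ahat >= 0)) {
    stop("natural parameter a_hat >= 0: model left the valid region",
         call. = FALSE)
  }
  list(mu = p$theta * exp(ahat) / (1 - exp(ahat)), theta = p$theta)
}

# vectorized NB draw for a matrix of natural parameters (rows = chains)
sample_visible_matrix <- function(Ahat, theta) {
  if (any(Ahat >= 0)) {
    stop("natural parameter a_hat >= 0: model left the valid region",
         call. = FALSE)
  }
  Mu <- sweep(exp(Ahat) / (1 - exp(Ahat)), 2, theta, "*")
  n <- nrow(Mu)
  X <- stats::rnbinom(length(Mu), size = rep(theta, each = n),
                      mu = as.vector(Mu))
  matrix(X, n, ncol(Mu))
}

#' Sample the visible layer given h1
#'
#' @inheritParams visible_conditional
#' @return Non-negative integer vector of per-gene counts.
#' @export
sample_visible <- function(h1, p) {
  cond <- visible_conditional(h1, p)
  stats::rnbinom(length(cond$mu), size = cond$theta, mu = cond$mu)
}

# all binary configurations of n units, as a 2^n x n matrix
binary_configs <- function(n) {
  if (n == 0) return(matrix(0, 1, 0))
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# Exact moments of the model distribution by exhaustive enumeration of the
# hidden configurations: the NB visible units integrate out analytically,
#   sum_x exp(a_hat x + log binom(x, theta)) = (1 - exp(a_hat))^(-theta),
# so for the small hidden layers used here (K, L <= 4) the joint over
# (h1, h2) and all expectations needed for training are closed-form.
scdbm_exact_moments <- function(p) {
  K <- length(p$b1); L <- length(p$b2)
  H1 <- binary_configs(K)
  H2 <- binary_configs(L)
  Ahat <- visible_natural(H1, p)                   # 2^K x M
  logZvis <- -as.vector((log1p(-exp(Ahat)) %*% p$theta))  # per h1 config
  Mu <- sweep(exp(Ahat) / (1 - exp(Ahat)), 2, p$theta, "*")
  lw <- outer(drop(H1 %*% p$b1) + logZvis, drop(H2 %*% p$b2), "+") +
    H1 %*% p$W2 %*% t(H2)                          # 2^K x 2^L
  lw <- lw - max(lw)
  P <- exp(lw) / sum(exp(lw))
  p1 <- rowSums(P)                                 # marginal over h1 configs
  p2 <- colSums(P)
  list(H1 = H1, H2 = H2, P = P, p1 = p1, p2 = p2, Mu = Mu,
       Eh1 = unname(drop(crossprod(H1, p1))),
       Eh2 = unname(drop(crossprod(H2, p2))),
       Eh1h2 = unname(t(H1) %*% P %*% H2),
       Ex = unname(drop(crossprod(Mu, p1))),
       Exh1 = unname(crossprod(Mu, p1 * H1)))
}

# Calibrate the hidden prior so the model's marginal over h1
# configurations matches a target occupancy (typically the aggregated
# data posterior). The mass ratio of two deep modes is exponential in
# small energy differences, so stochastic training leaves the latent
# prior orbiting the target; this final deterministic fit of (b1, b2, W2)
# pins it. Gradient descent on the cross-entropy between the target and
# the enumerated marginal.
calibrate_hidden_prior <- function(p, occ_target, iters = 400L, lr = 0.5) {
  K <- length(p$b1); L <- length(p$b2)
  H1 <- binary_configs(K)
  H2 <- binary_configs(L)
  Ahat <- visible_natural(H1, p)
  lz <- -as.vector(log1p(-exp(Ahat)) %*% p$theta)
  occ_target <- occ_target / sum(occ_target)
  for (it in seq_len(iters)) {
    tij <- outer(rep(0, nrow(H1)), drop(H2 %*% p$b2), "+") +
      H1 %*% p$W2 %*% t(H2)
    mx <- apply(tij, 1, max)
    lse2 <- mx + log(rowSums(exp(tij - mx)))
    g <- drop(H1 %*% p$b1) + lz + lse2
    p1 <- exp(g - max(g))
    p1 <- p1 / sum(p1)
    Pj_i <- exp(tij - lse2)
    resid <- p1 - occ_target                      # d(-CE)/dg per config
    Eh2_i <- Pj_i %*% H2                          # 2^K x L
    p$b1 <- p$b1 - lr * drop(crossprod(H1, resid))
    p$b2 <- p$b2 - lr * drop(crossprod(Eh2_i, resid))
    p$W2 <- p$W2 - lr * crossprod(H1, resid * Eh2_i)
    if (max(abs(resid)) < 1e-6) break
  }
  p
}

# activations (rows = states)
hidden1_activation <- function(X, H2, p) {
  sweep(X %*% p$W1 + H2 %*% t(p$W2), 2, p$b1, "+")
}
hidden2_activation <- function(H1, p) {
  sweep(H1 %*% p$W2, 2, p$b2, "+")
}

#' Sample the first hidden layer given x and h2
#'
#' Independent Bernoulli draws with success probability
#' `sigmoid(b1_k + sum_m W1_mk x_m + sum_l W2_kl h2_l)`.
#'
#' @param x Count vector.
#' @param h2 Binary vector.
#' @param p An [scdbm_params()] object.
#' @return Binary vector of length `K`.
#' @export
sample_hidden1 <- function(x, h2, p) {
  pr <- stats::plogis(drop(hidden1_activation(matrix(x, 1), matrix(h2, 1), p)))
  as.integer(stats::runif(length(pr)) < pr)
}

#' Sample the second hidden layer given h1
#'
#' Independent Bernoulli draws with success probability
#' `sigmoid(b2_l + sum_k W2_kl h1_k)`.
#'
#' @param h1 Binary vector.
#' @param p An [scdbm_params()] object.
#' @return Binary vector of length `L`.
#' @export
sample_hidden2 <- function(h1, p) {
  pr <- stats::plogis(drop(hidden2_activation(matrix(h1, 1), p)))
  as.integer(stats::runif(length(pr)) < pr)
}

#' Training configuration for the scDBM
#'
#' @param epochs Joint-training epochs.
#' @param learning_rate Step size for stochastic gradient ascent. Kept
#'   small because gradients live on the raw count scale while `a` lives
#'   on the log scale.
#' @param batch_size Minibatch size.
#' @param cd_steps Gibbs sweeps per persistent-contrastive-divergence
#'   update.
#' @param pretrain_epochs Greedy layer-wise RBM pretraining epochs.
#' @param theta_refresh_every Refresh the inverse dispersion by regularized
#'   Fisher scoring every this many epochs.
#' @param lambda_reg Regularization strength passed to the Fisher-scoring
#'   refresh.
#' @param n_hidden1,n_hidden2 Hidden layer widths `K` and `L`; small latent
#'   spaces (2-4 units) suffice for cluster structure.
#' @param n_chains Number of persistent negative-phase chains.
#' @param mean_field_iters,mean_field_tol Fixed-point iterations and
#'   tolerance for the mean-field positive phase.
#' @param theta_mu Means fed to the dispersion refresh: mean-field model
#'   reconstruction per cell (`"reconstruction"`) or the per-gene empirical
#'   mean (`"empirical"`).
#' @param negative_phase `"exact"` (default): the model-side statistics
#'   are computed in closed form by enumerating all `2^(K+L)` hidden
#'   configurations after integrating out the NB visible units -- exact,
#'   deterministic, and free of chain-mixing artifacts for the small
#'   latent spaces used here; `"pcd"`: persistent contrastive-divergence
#'   chains; `"cd"`: chains restarted at the current minibatch.
#' @param constrain_w2 Also clip the hidden-to-hidden weights to be
#'   non-positive. Off by default: only the visible-layer weights need the
#'   sign constraint for model validity.
#' @param calibrate_prior After the gradient epochs, refit the hidden
#'   prior (b1, b2, W2) so the model's marginal over hidden
#'   configurations matches the aggregated data posterior occupancy;
#'   stabilizes mixture proportions, which are exponentially sensitive to
#'   small energy differences. Only available when the hidden space is
#'   enumerable.
#' @param seed Integer seed controlling initialization and training noise.
#' @return A list of class `"scdbm_config"`.
#' @export
scdbm_config <- function(epochs = 60L, learning_rate = 0.02,
                         batch_size = 32L, cd_steps = 5L,
                         pretrain_epochs = 0L, theta_refresh_every = 5L,
                         lambda_reg = 5, n_hidden1 = 3L,
                         n_hidden2 = n_hidden1, n_chains = 100L,
                         mean_field_iters = 10L, mean_field_tol = 1e-4,
                         theta_mu = c("reconstruction", "empirical"),
                         negative_phase = c("exact", "pcd", "cd"),
                         constrain_w2 = FALSE, calibrate_prior = TRUE,
                         seed = 1L) {
  stopifnot(theta_refresh_every >= 1, learning_rate > 0, epochs >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 cd_steps = as.integer(cd_steps),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 theta_refresh_every = as.integer(theta_refresh_every),
                 lambda_reg = lambda_reg, n_hidden1 = as.integer(n_hidden1),
                 n_hidden2 = as.integer(n_hidden2),
                 n_chains = as.integer(n_chains),
                 mean_field_iters = as.integer(mean_field_iters),
                 mean_field_tol = mean_field_tol,
                 theta_mu = match.arg(theta_mu),
                 negative_phase = match.arg(negative_phase),
                 constrain_w2 = isTRUE(constrain_w2),
                 calibrate_prior = isTRUE(calibrate_prior),
                 seed = as.integer(seed)),
            class = "scdbm_config")
}

# Exact posterior over hidden configurations given data rows of X
# (enumerable for small K + L): returns per-cell posterior expectations of
# h1 and h2, the summed joint config table, and the posterior-predictive
# NB mean per cell.
scdbm_exact_posterior <- function(X, p) {
  K <- length(p$b1); L <- length(p$b2)
  H1 <- binary_configs(K)
  H2 <- binary_configs(L)
  s1 <- sweep(X %*% p$W1, 2, p$b1, "+") %*% t(H1)     # n x 2^K
  tij <- outer(rep(0, nrow(H1)), drop(H2 %*% p$b2), "+") +
    H1 %*% p$W2 %*% t(H2)                             # 2^K x 2^L
  # collapse h2 analytically: log sum over j of exp(t_ij)
  lse2 <- apply(tij, 1, function(v) {
    m <- max(v); m + log(sum(exp(v - m)))
  })
  lq <- sweep(s1, 2, lse2, "+")
  lq <- lq - apply(lq, 1, max)
  Q1 <- exp(lq)
  Q1 <- Q1 / rowSums(Q1)                              # n x 2^K
  Pj_given_i <- exp(tij - apply(tij, 1, function(v) {
    m <- max(v); m + log(sum(exp(v - m)))
  }))
  Pj_given_i <- Pj_given_i / rowSums(Pj_given_i)
  Qsum <- crossprod(Q1, matrix(1, nrow(X), 1))        # 2^K x 1 occupancy
  Qsum <- as.vector(Qsum) * Pj_given_i                # 2^K x 2^L
  Ahat <- visible_natural(H1, p)
  Mu_cfg <- sweep(exp(Ahat) / (1 - exp(Ahat)), 2, p$theta, "*")
  list(Q1 = Q1, M1 = Q1 %*% H1, M2 = Q1 %*% (Pj_given_i %*% H2),
       Qsum = Qsum, Mu = Q1 %*% Mu_cfg, H1 = H1, H2 = H2)
}

# mean-field fixed point for (h1, h2) given data X
scdbm_mean_field <- function(X, p, iters = 10L, tol = 1e-4) {
  M1 <- stats::plogis(sweep(X %*% p$W1, 2, p$b1, "+"))
  M2 <- stats::plogis(hidden2_activation(M1, p))
  for (i in seq_len(iters)) {
    M1_new <- stats::plogis(hidden1_activation(X, M2, p))
    M2 <- stats::plogis(hidden2_activation(M1_new, p))
    if (max(abs(M1_new - M1)) < tol) {
      M1 <- M1_new
      break
    }
    M1 <- M1_new
  }
  list(M1 = M1, M2 = M2)
}

# model reconstruction means per cell: posterior-predictive NB mean when
# the hidden space is enumerable, otherwise the mean-field expectation of
# h1 plugged into the visible conditional
scdbm_reconstruct_mu <- function(X, p, cfg) {
  if (length(p$b1) + length(p$b2) <= 12) {
    return(scdbm_exact_posterior(X, p)$Mu)
  }
  mf <- scdbm_mean_field(X, p, cfg$mean_field_iters, cfg$mean_field_tol)
  Ahat <- visible_natural(mf$M1, p)
  Ahat <- pmin(Ahat, -p$eps)
  sweep(exp(Ahat) / (1 - exp(Ahat)), 2, p$theta, "*")
}

# Data-driven initialization. The visible bias is set to the natural
# parameter of the per-gene upper envelope over K k-means cluster
# profiles, and each column of W1 to the (non-positive) offset taking the
# envelope down to one cluster's profile, so that the one-hot hidden
# configurations reproduce the K crude cluster means. Hidden biases are
# set from the analytic visible normalizer so those configurations start
# with mass proportional to the cluster sizes.
scdbm_init <- function(X, cfg, theta_bounds = c(0.01, 1000)) {
  M <- ncol(X)
  K <- cfg$n_hidden1
  theta <- vapply(seq_len(M), function(m) theta_mom(X[, m], theta_bounds),
                  numeric(1))
  zero_genes <- colSums(X) == 0
  if (any(zero_genes)) {
    warning(sum(zero_genes), " all-zero gene(s): theta set to ceiling ",
            theta_bounds[2], call. = FALSE)
    theta[zero_genes] <- theta_bounds[2]
  }
  lib <- rowSums(X)
  lib[lib == 0] <- 1
  norm <- log1p(X * (stats::median(lib) / lib))
  km <- tryCatch(stats::kmeans(norm, centers = K, nstart = 5,
                               iter.max = 50),
                 error = function(e) NULL)
  nat <- function(mu) log(mu) - log(mu + theta)  # mu = theta e^a/(1-e^a)
  if (is.null(km)) {
    mu_cl <- matrix(pmax(colMeans(X), 1e-3), K, M, byrow = TRUE)
    sizes <- rep(nrow(X) / K, K)
  } else {
    mu_cl <- t(vapply(seq_len(K), function(kk) {
      pmax(colMeans(X[km$cluster == kk, , drop = FALSE]), 1e-3)
    }, numeric(M)))
    sizes <- pmax(km$size, 1)
  }
  env <- pmax(apply(mu_cl, 2, max), 1e-3)
  a <- nat(env)
  W1 <- pmin(t(nat(mu_cl)) - a, 0)                     # M x K
  log_zvis <- function(ahat) -sum(theta * log1p(-exp(ahat)))
  lz_off <- log_zvis(a)
  pi_k <- pmin(pmax(sizes / sum(sizes), 0.02), 0.98)
  # +3 pushes the all-off (envelope-profile) configuration down to a few
  # percent of the mass at initialization
  b1 <- vapply(seq_len(K), function(kk) {
    (lz_off - log_zvis(a + W1[, kk])) + log(pi_k[kk]) + 3
  }, numeric(1))
  # second layer initialized as a soft winner-take-all prior over the
  # first hidden layer: each h2 unit excites one h1 unit and inhibits the
  # others, boosting one-hot h1 configurations over the all-off and
  # multi-on ones (a correlation pattern single-layer biases cannot carry)
  if (cfg$n_hidden2 == K) {
    W2 <- 6 * (2 * diag(K) - 1)
  } else {
    W2 <- matrix(stats::rnorm(K * cfg$n_hidden2, 0, 0.5), K)
  }
  apply_constraints(list(a = a, b1 = b1,
                         b2 = rep(0, cfg$n_hidden2), W1 = W1, W2 = W2,
                         theta = theta, eps = 1e-10))
}

check_finite <- function(p, where) {
  ok <- all(vapply(p[c("a", "b1", "b2", "W1", "W2", "theta")],
                   function(z) all(is.finite(z)), logical(1)))
  if (!ok) stop("non-finite parameter during training at ", where,
                call. = FALSE)
}

#' Train a negative-binomial deep Boltzmann machine
#'
#' Three stages: (i) per-gene inverse dispersion initialized by the method
#' of moments; (ii) greedy layer-wise RBM pretraining with one-step
#' contrastive divergence; (iii) joint training by persistent contrastive
#' divergence, with a mean-field positive phase and a Rao-Blackwellized
#' negative phase, applying the feasibility constraints after every
#' gradient step. The inverse dispersion is held fixed between refreshes
#' and re-estimated by regularized Fisher scoring every
#' `theta_refresh_every` epochs.
#'
#' @param cm A [count_matrix()] of training cells.
#' @param cfg An [scdbm_config()].
#' @param warm_start Optional `"scdbm"` fit or parameter list to continue
#'   training from (skips initialization and pretraining).
#' @return An object of class `"scdbm"`: list with `params`
#'   ([scdbm_params()]), `config`, and `history` (tibble of per-epoch
#'   reconstruction moment error).
#' @export
train_scdbm <- function(cm, cfg = scdbm_config(), warm_start = NULL) {
  X <- unclass(cm)
  storage.mode(X) <- "double"
  if (!nrow(X) || !ncol(X)) stop("empty count matrix", call. = FALSE)
  if (inherits(warm_start, "scdbm")) warm_start <- warm_start$params
  withr::with_seed(cfg$seed, train_scdbm_impl(X, cm, cfg, warm_start))
}

train_scdbm_impl <- function(X, cm, cfg, warm_start = NULL) {
  n <- nrow(X)
  lr <- cfg$learning_rate
  p <- if (is.null(warm_start)) scdbm_init(X, cfg) else
    unclass(warm_start)[c("a", "b1", "b2", "W1", "W2", "theta", "eps")]
  history <- list()
  fcfg <- fisher_scoring_config(lambda_reg = cfg$lambda_reg)

  if (cfg$epochs == 0 && cfg$pretrain_epochs == 0) {
    return(new_scdbm(p, cfg, history, cm))
  }

  batches <- function() {
    idx <- sample.int(n)
    split(idx, ceiling(seq_along(idx) / cfg$batch_size))
  }

  # --- greedy layer-wise pretraining (CD-1) ---
  pretrain_epochs <- if (is.null(warm_start)) cfg$pretrain_epochs else 0L
  precond0 <- 1 / (pmax(colMeans(X), 1e-3) + 1)
  mu_cap0 <- 2 * max(X) + 10
  clip10 <- function(g) pmin(pmax(g, -1), 1)
  for (ep in seq_len(pretrain_epochs)) {
    for (b in batches()) {
      Xb <- X[b, , drop = FALSE]
      nb <- nrow(Xb)
      P1 <- stats::plogis(sweep(Xb %*% p$W1, 2, p$b1, "+"))
      H1 <- matrix(as.integer(stats::runif(length(P1)) < P1), nb)
      Ahat <- pmin(visible_natural(H1, p), -p$eps)
      Mu <- pmin(sweep(exp(Ahat) / (1 - exp(Ahat)), 2, p$theta, "*"),
                 mu_cap0)
      P1n <- stats::plogis(sweep(Mu %*% p$W1, 2, p$b1, "+"))
      p$a <- p$a + lr * clip10(precond0 * (colMeans(Xb) - colMeans(Mu)))
      p$W1 <- p$W1 + lr * clip10(precond0 *
        (crossprod(Xb, P1) - crossprod(Mu, P1n)) / nb)
      p$b1 <- p$b1 + lr * (colMeans(P1) - colMeans(P1n))
      p <- apply_constraints(p, p$eps)
      p$W1 <- pmax(p$W1, -8)
      p$a <- pmin(pmax(p$a, -30), log(mu_cap0 / (mu_cap0 + p$theta)))
    }
    check_finite(p, paste0("pretrain layer-1 epoch ", ep))
  }
  # layer 2: binary RBM on sampled layer-1 activities (faster binary rate)
  lr2 <- max(lr, 0.05)
  for (ep in seq_len(pretrain_epochs)) {
    P1 <- stats::plogis(sweep(X %*% p$W1, 2, p$b1, "+"))
    H1d <- matrix(as.integer(stats::runif(length(P1)) < P1), n)
    for (b in batches()) {
      H1b <- H1d[b, , drop = FALSE]
      nb <- nrow(H1b)
      P2 <- stats::plogis(hidden2_activation(H1b, p))
      H2 <- matrix(as.integer(stats::runif(length(P2)) < P2), nb)
      P1r <- stats::plogis(sweep(H2 %*% t(p$W2), 2, p$b1, "+"))
      P2r <- stats::plogis(hidden2_activation(P1r, p))
      p$W2 <- p$W2 + lr2 * (crossprod(H1b, P2) - crossprod(P1r, P2r)) / nb
      p$b2 <- p$b2 + lr2 * (colMeans(P2) - colMeans(P2r))
    }
    check_finite(p, paste0("pretrain layer-2 epoch ", ep))
  }

  # --- persistent chains for the negative phase (chain-based modes) ---
  if (cfg$negative_phase != "exact") {
    C <- cfg$n_chains
    Ahat0 <- matrix(p$a, C, length(p$a), byrow = TRUE)
    Xc <- sample_visible_matrix(Ahat0, p$theta)
    H2c <- matrix(as.integer(stats::runif(C * cfg$n_hidden2) < 0.5), C)
  }

  # gradients of a and W1 live on the raw count scale while the
  # parameters live on the natural (log) scale; dividing by the per-gene
  # mean turns them into relative errors, which are additionally clipped
  # to +-1: near a -> 0- the conditional mean diverges, and unclipped
  # steps oscillate between explosion and collapse
  precond <- 1 / (pmax(colMeans(X), 1e-3) + 1)
  mu_cap <- 2 * max(X) + 10
  clip1 <- function(g) pmin(pmax(g, -1), 1)
  exact_pos <- (cfg$n_hidden1 + cfg$n_hidden2) <= 12

  for (ep in seq_len(cfg$epochs)) {
    # linear decay to 20% of the initial step size
    lr <- cfg$learning_rate *
      (1 - 0.8 * (ep - 1) / max(1, cfg$epochs - 1))
    for (b in batches()) {
      Xb <- X[b, , drop = FALSE]
      nb <- nrow(Xb)
      if (exact_pos) {
        ps <- scdbm_exact_posterior(Xb, p)
        mf <- list(M1 = ps$Q1 %*% ps$H1, M2 = ps$M2)
        pos_h1h2 <- t(ps$H1) %*% (ps$Qsum %*% ps$H2) / nb
      } else {
        mf <- scdbm_mean_field(Xb, p, cfg$mean_field_iters,
                               cfg$mean_field_tol)
        pos_h1h2 <- crossprod(mf$M1, mf$M2) / nb
      }
      if (cfg$negative_phase == "exact") {
        mom <- scdbm_exact_moments(p)
        neg <- list(x = pmin(mom$Ex, mu_cap), h1 = mom$Eh1, h2 = mom$Eh2,
                    xh1 = pmin(mom$Exh1, mu_cap), h1h2 = mom$Eh1h2)
      } else {
        if (cfg$negative_phase == "cd") {
          # restart the negative chains at the minibatch
          Xc <- Xb
          H2c <- matrix(as.integer(stats::runif(nb * cfg$n_hidden2) <
                                     as.vector(mf$M2)), nb)
          C <- nb
        }
        for (s in seq_len(cfg$cd_steps)) {
          P1c <- stats::plogis(hidden1_activation(Xc, H2c, p))
          H1c <- matrix(as.integer(stats::runif(length(P1c)) < P1c), C)
          P2c <- stats::plogis(hidden2_activation(H1c, p))
          H2c <- matrix(as.integer(stats::runif(length(P2c)) < P2c), C)
          Ahat <- visible_natural(H1c, p)
          Muc <- sweep(exp(Ahat) / (1 - exp(Ahat)), 2, p$theta, "*")
          Muc <- pmin(Muc, mu_cap)  # numerical guard, see clip note above
          Xc <- matrix(stats::rnbinom(length(Muc),
                                      size = rep(p$theta, each = C),
                                      mu = as.vector(Muc)), C)
        }
        neg <- list(x = colMeans(Muc), h1 = colMeans(P1c),
                    h2 = colMeans(P2c), xh1 = crossprod(Muc, H1c) / C,
                    h1h2 = crossprod(H1c, P2c) / C)
      }
      p$a <- p$a + lr * clip1(precond * (colMeans(Xb) - neg$x))
      p$W1 <- p$W1 + lr * clip1(precond *
        (crossprod(Xb, mf$M1) / nb - neg$xh1))
      p$b1 <- p$b1 + lr * (colMeans(mf$M1) - neg$h1)
      p$b2 <- p$b2 + lr * (colMeans(mf$M2) - neg$h2)
      p$W2 <- p$W2 + lr * (pos_h1h2 - neg$h1h2)
      p <- apply_constraints(p, p$eps)
      if (cfg$constrain_w2) p$W2 <- pmin(p$W2, 0)
      # numerical guards: exp(-8) already silences a gene completely,
      # unbounded weights make chains degenerate, and the bias ceiling
      # keeps the implied bias-only mean below mu_cap
      p$W1 <- pmax(p$W1, -8)
      p$a <- pmin(pmax(p$a, -30), log(mu_cap / (mu_cap + p$theta)))
      check_finite(p, paste0("epoch ", ep, " batch of ", nb))
    }
    Mu_rec <- scdbm_reconstruct_mu(X, p, cfg)
    recon_err <- mean(abs(colMeans(Mu_rec) - colMeans(X)) /
                        (colMeans(X) + 1e-8))
    history[[ep]] <- tibble::tibble(epoch = ep, recon_moment_error = recon_err)
    if (ep %% cfg$theta_refresh_every == 0) {
      Mu_theta <- if (cfg$theta_mu == "reconstruction") Mu_rec else
        matrix(pmax(colMeans(X), 1e-3), n, ncol(X), byrow = TRUE)
      theta_new <- p$theta
      for (m in seq_len(ncol(X))) {
        if (all(X[, m] == 0)) next  # keep ceiling from initialization
        theta_new[m] <- suppressWarnings(
          as.numeric(estimate_theta(X[, m], pmax(Mu_theta[, m], 1e-6), fcfg))
        )
      }
      p$theta <- theta_new
    }
  }
  if (cfg$calibrate_prior && exact_pos && cfg$epochs > 0) {
    occ <- colMeans(scdbm_exact_posterior(X, p)$Q1)
    p <- calibrate_hidden_prior(p, occ)
  }
  new_scdbm(p, cfg, history, cm)
}

new_scdbm <- function(p, cfg, history, cm) {
  params <- scdbm_params(p$a, p$b1, p$b2, p$W1, p$W2, p$theta, p$eps)
  structure(list(params = params, config = cfg,
                 history = dplyr::bind_rows(history),
                 genes = colnames(cm), n_cells_trained = nrow(cm)),
            class = "scdbm")
}

#' @export
print.scdbm <- function(x, ...) {
  cat("<scdbm> negative-binomial deep Boltzmann machine\n")
  cat("  genes:", length(x$params$a),
      " hidden: K =", length(x$params$b1), ", L =", length(x$params$b2), "\n")
  cat("  trained on", x$n_cells_trained, "cells for", x$config$epochs,
      "epochs\n")
  invisible(x)
}

#' Generate synthetic cells from a trained scDBM by Gibbs sampling
#'
#' Runs `n_cells` independent chains, each initialized from the bias-only
#' negative-binomial marginal and advanced `burn_in + gibbs_steps`
#' alternating sweeps through the three conditionals (visible given h1,
#' h1 given x and h2, h2 given h1); the final visible state of each chain
#' is returned as one synthetic cell.
#'
#' @param object An `"scdbm"` fit or an [scdbm_params()] object.
#' @param n_cells Number of synthetic cells.
#' @param gibbs_steps Sweeps after burn-in (>= 1).
#' @param burn_in Burn-in sweeps per chain.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A [count_matrix()] of `n_cells` x `M` counts.
#' @export
scdbm_generate <- function(object, n_cells, gibbs_steps = 1L, burn_in = 100L,
                           seed = 1L) {
  p <- if (inherits(object, "scdbm")) object$params else object
  genes <- if (inherits(object, "scdbm")) object$genes else
    paste0("gene", seq_along(p$a))
  if (gibbs_steps < 1) stop("gibbs_steps must be >= 1", call. = FALSE)
  # re-validate invariants before sampling
  p <- scdbm_params(p$a, p$b1, p$b2, p$W1, p$W2, p$theta, p$eps)
  M <- length(p$a)
  if (n_cells == 0) {
    return(count_matrix(matrix(integer(0), 0, M, dimnames = list(NULL, genes))))
  }
  K <- length(p$b1); L <- length(p$b2)
  X <- withr::with_seed(seed, {
    if (K + L <= 12) {
      # initialize each chain at an exact draw from the hidden joint
      # (enumerable for small latent spaces), so the Gibbs chains start
      # at stationarity and mode proportions are unbiased
      mom <- scdbm_exact_moments(p)
      cfg_idx <- sample.int(length(mom$P), n_cells, replace = TRUE,
                            prob = as.vector(mom$P))
      i1 <- (cfg_idx - 1L) %% nrow(mom$P) + 1L
      i2 <- (cfg_idx - 1L) %/% nrow(mom$P) + 1L
      H2c <- mom$H2[i2, , drop = FALSE]
      Xc <- sample_visible_matrix(visible_natural(
        mom$H1[i1, , drop = FALSE], p), p$theta)
    } else {
      Ahat0 <- matrix(p$a, n_cells, M, byrow = TRUE)
      Xc <- sample_visible_matrix(Ahat0, p$theta)
      H2c <- matrix(as.integer(stats::runif(n_cells * L) < 0.5), n_cells)
    }
    for (s in seq_len(burn_in + gibbs_steps)) {
      P1 <- stats::plogis(hidden1_activation(Xc, H2c, p))
      H1 <- matrix(as.integer(stats::runif(length(P1)) < P1), n_cells)
      P2 <- stats::plogis(hidden2_activation(H1, p))
      H2c <- matrix(as.integer(stats::runif(length(P2)) < P2), n_cells)
      Xc <- sample_visible_matrix(visible_natural(H1, p), p$theta)
    }
    Xc
  })
  count_matrix(X, paste0("syn", seq_len(n_cells)), genes)
}

#' Save / load an scDBM checkpoint
#'
#' Checkpoints are versioned JSON holding all six parameter arrays plus
#' the training configuration, loadable for generation without retraining.
#'
#' @param fit An `"scdbm"` object.
#' @param path Output path.
#' @return `read_scdbm()` returns the restored `"scdbm"` object.
#' @export
write_scdbm <- function(fit, path) {
  payload <- list(
    format = "scpilot-scdbm", version = 1L,
    genes = fit$genes, n_cells_trained = fit$n_cells_trained,
    params = fit$params[c("a", "b1", "b2", "W1", "W2", "theta", "eps")],
    config = unclass(fit$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scdbm
#' @export
read_scdbm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "scpilot-scdbm")) {
    stop("not an scDBM checkpoint: ", path, call. = FALSE)
  }
  pj <- j$params
  params <- scdbm_params(pj$a, pj$b1, pj$b2, as.matrix(pj$W1),
                         as.matrix(pj$W2), pj$theta, pj$eps)
  cfg <- do.call(scdbm_config, j$config[setdiff(names(j$config), NULL)])
  structure(list(params = params, config = cfg, history = tibble::tibble(),
                 genes = j$genes, n_cells_trained = j$n_cells_trained),
            class = "scdbm")
}
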