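#' Training configuration for the negative-binomial VAE
#'
#' A minimal variational autoencoder for counts: one ReLU hidden layer in
#' both encoder and decoder, a Gaussian latent `z` (default 10
#' dimensions), a one-dimensional Gaussian log library size `l`, and a
#' negative-binomial reconstruction likelihood whose mean is the softmax
#' decoder output (per-gene transcript proportions) scaled by `exp(l)`.
#' No batch covariate and no zero-inflation.
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param hidden_width Width of the single hidden layer.
#' @param latent_dim Dimension of `z`.
#' @param seed Integer seed.
#' @return A list of class `"nbvae_config"`.
#' @export
nbvae_config <- function(epochs = 400L, learning_rate = 1e-3,
                         batch_size = 128L, hidden_width = 128L,
                         latent_dim = 10L, seed = 1L) {
  stopifnot(epochs > 0, learning_rate > 0, batch_size > 0,
            hidden_width > 0, latent_dim >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 hidden_width = as.integer(hidden_width),
                 latent_dim = as.integer(latent_dim),
                 seed = as.integer(seed)),
            class = "nbvae_config")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

nbvae_init <- function(G, H, Z) {
  wn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(
    We = wn(G, H), be = rep(0, H),
    Wmz = wn(H, Z), bmz = rep(0, Z),
    Wvz = wn(H, Z), bvz = rep(-2, Z),
    wml = wn(H, 1), bml = 0,
    wvl = wn(H, 1), bvl = -2,
    Wd = wn(Z, H), bd = rep(0, H),
    Wp = wn(H, G), bp = rep(0, G),
    log_theta = rep(0, G)
  )
}

# forward pass through the encoder; X is raw counts
nbvae_encode <- function(w, X) {
  Xin <- log1p(X)
  He_pre <- sweep(Xin %*% w$We, 2, w$be, "+")
  He <- relu(He_pre)
  clip <- function(v) pmin(pmax(v, -8), 8)
  list(Xin = Xin, He_pre = He_pre, He = He,
       muz = sweep(He %*% w$Wmz, 2, w$bmz, "+"),
       lvz = clip(sweep(He %*% w$Wvz, 2, w$bvz, "+")),
       mul = drop(He %*% w$wml) + w$bml,
       lvl = clip(drop(He %*% w$wvl) + w$bvl))
}

# decoder: latent z (B x Z) and log library l (B) to NB means
nbvae_decode <- function(w, z, l) {
  Hd_pre <- sweep(z %*% w$Wd, 2, w$bd, "+")
  Hd <- relu(Hd_pre)
  S <- sweep(Hd %*% w$Wp, 2, w$bp, "+")
  rho <- softmax_rows(S)
  mu <- pmax(rho * exp(l), 1e-8)
  list(Hd_pre = Hd_pre, Hd = Hd, rho = rho, mu = mu)
}

# one minibatch: returns gradients of the per-cell-mean ELBO and its value
nbvae_grad <- function(w, X, prior) {
  B <- nrow(X)
  enc <- nbvae_encode(w, X)
  Ez <- matrix(stats::rnorm(length(enc$muz)), B)
  El <- stats::rnorm(B)
  z <- enc$muz + exp(0.5 * enc$lvz) * Ez
  l <- enc$mul + exp(0.5 * enc$lvl) * El
  dec <- nbvae_decode(w, z, l)
  theta <- exp(w$log_theta)
  Th <- matrix(theta, B, length(theta), byrow = TRUE)
  mu <- dec$mu

  recon <- rowSums(lgamma(X + Th) - lgamma(X + 1) - lgamma(Th) +
                     Th * log(Th / (Th + mu)) + X * log(mu / (Th + mu)))
  kl_z <- 0.5 * rowSums(exp(enc$lvz) + enc$muz^2 - 1 - enc$lvz)
  v0 <- prior$l_var
  kl_l <- 0.5 * ((exp(enc$lvl) + (enc$mul - prior$l_mu)^2) / v0 - 1 -
                   enc$lvl + log(v0))
  elbo <- mean(recon - kl_z - kl_l)

  # reconstruction gradients
  dmu <- X / mu - (X + Th) / (Th + mu)
  dl_rec <- rowSums(dmu * mu)
  drho <- dmu * exp(l)
  dS <- dec$rho * (drho - rowSums(drho * dec$rho))
  dlog_theta <- colSums(Th * (digamma(X + Th) - digamma(Th) +
                                log(Th / (Th + mu)) + 1 -
                                (X + Th) / (Th + mu))) / B
  dHd <- dS %*% t(w$Wp)
  dHd <- dHd * (dec$Hd_pre > 0)
  dz <- dHd %*% t(w$Wd)
  # KL gradients fold in here (objective = recon - kl_z - kl_l)
  dmuz <- dz - enc$muz
  lvz_in <- abs(enc$lvz) < 8
  dlvz <- (dz * Ez * 0.5 * exp(0.5 * enc$lvz) -
             0.5 * (exp(enc$lvz) - 1)) * lvz_in
  dmul <- dl_rec - (enc$mul - prior$l_mu) / v0
  lvl_in <- abs(enc$lvl) < 8
  dlvl <- (dl_rec * El * 0.5 * exp(0.5 * enc$lvl) -
             0.5 * (exp(enc$lvl) / v0 - 1)) * lvl_in
  dHe <- dmuz %*% t(w$Wmz) + dlvz %*% t(w$Wvz) +
    outer(dmul, drop(w$wml)) + outer(dlvl, drop(w$wvl))
  dHe <- dHe * (enc$He_pre > 0)

  grads <- list(
    We = crossprod(enc$Xin, dHe) / B, be = colSums(dHe) / B,
    Wmz = crossprod(enc$He, dmuz) / B, bmz = colSums(dmuz) / B,
    Wvz = crossprod(enc$He, dlvz) / B, bvz = colSums(dlvz) / B,
    wml = crossprod(enc$He, dmul) / B, bml = sum(dmul) / B,
    wvl = crossprod(enc$He, dlvl) / B, bvl = sum(dlvl) / B,
    Wd = crossprod(z, dHd) / B, bd = colSums(dHd) / B,
    Wp = crossprod(dec$Hd, dS) / B, bp = colSums(dS) / B,
    log_theta = dlog_theta
  )
  list(grads = grads, elbo = elbo)
}

#' Train the negative-binomial VAE
#'
#' Maximizes the evidence lower bound
#' `E_q log p(x | z, l) - KL(q(z|x) || p(z)) - KL(q(l|x) || p(l))`
#' by stochastic gradient ascent with the reparameterization trick and
#' Adam. The library-size prior `p(l)` is Gaussian with mean and variance
#' taken from the log total counts of the training cells; the per-gene
#' inverse dispersion is learned as a free log-parameterized vector.
#'
#' @param cm A [count_matrix()] of training cells.
#' @param cfg An [nbvae_config()].
#' @return An object of class `"nbvae"`: weights, config, library-size
#'   prior (`l_mu`, `l_sd`), gene ids, and a per-epoch ELBO history tibble.
#' @export
train_vae <- function(cm, cfg = nbvae_config()) {
  X <- unclass(cm)
  storage.mode(X) <- "double"
  if (!nrow(X) || !ncol(X)) stop("empty count matrix", call. = FALSE)
  lib <- log(pmax(rowSums(X), 1))
  prior <- list(l_mu = mean(lib), l_sd = max(stats::sd(lib), 1e-2))
  prior$l_var <- prior$l_sd^2
  withr::with_seed(cfg$seed, train_vae_impl(X, cm, cfg, prior))
}

train_vae_impl <- function(X, cm, cfg, prior) {
  n <- nrow(X)
  w <- nbvae_init(ncol(X), cfg$hidden_width, cfg$latent_dim)
  mstate <- lapply(w, function(p) p * 0)
  vstate <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  t <- 0
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_elbo <- 0
    for (b in batches) {
      g <- nbvae_grad(w, X[b, , drop = FALSE], prior)
      if (!is.finite(g$elbo)) {
        stop("non-finite ELBO at epoch ", ep, call. = FALSE)
      }
      ep_elbo <- ep_elbo + g$elbo * length(b)
      t <- t + 1
      for (nm in names(w)) {
        gr <- g$grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
        mhat <- mstate[[nm]] / (1 - b1^t)
        vhat <- vstate[[nm]] / (1 - b2^t)
        w[[nm]] <- w[[nm]] + cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
      w$log_theta <- pmin(pmax(w$log_theta, log(0.01)), log(1000))
    }
    history[ep] <- ep_elbo / n
  }
  structure(list(weights = w, config = cfg, prior = prior,
                 genes = colnames(cm), n_cells_trained = n,
                 history = tibble::tibble(epoch = seq_len(cfg$epochs),
                                          elbo = history)),
            class = "nbvae")
}

#' @export
print.nbvae <- function(x, ...) {
  cat("<nbvae> negative-binomial variational autoencoder\n")
  cat("  genes:", length(x$genes), " latent dim:", x$config$latent_dim, "\n")
  cat("  trained on", x$n_cells_trained, "cells for", x$config$epochs,
      "epochs; final ELBO/cell:",
      round(utils::tail(x$history$elbo, 1), 2), "\n")
  invisible(x)
}

#' Monte-Carlo ELBO of an NB-VAE on a dataset
#'
#' @param fit An `"nbvae"` object.
#' @param cm A [count_matrix()] with the fit's genes.
#' @param seed Integer seed for the reparameterization draw.
#' @return A one-row tibble with `elbo`, `recon`, `kl_z`, `kl_l`
#'   (per-cell means; the KL terms are closed-form and non-negative).
#' @export
vae_elbo <- function(fit, cm, seed = 1L) {
  X <- unclass(cm)
  storage.mode(X) <- "double"
  w <- fit$weights
  prior <- fit$prior
  withr::with_seed(seed, {
    enc <- nbvae_encode(w, X)
    Ez <- matrix(stats::rnorm(length(enc$muz)), nrow(X))
    El <- stats::rnorm(nrow(X))
    z <- enc$muz + exp(0.5 * enc$lvz) * Ez
    l <- enc$mul + exp(0.5 * enc$lvl) * El
    dec <- nbvae_decode(w, z, l)
    theta <- exp(w$log_theta)
    Th <- matrix(theta, nrow(X), length(theta), byrow = TRUE)
    recon <- rowSums(lgamma(X + Th) - lgamma(X + 1) - lgamma(Th) +
                       Th * log(Th / (Th + dec$mu)) +
                       X * log(dec$mu / (Th + dec$mu)))
    kl_z <- 0.5 * rowSums(exp(enc$lvz) + enc$muz^2 - 1 - enc$lvz)
    v0 <- prior$l_var
    kl_l <- 0.5 * ((exp(enc$lvl) + (enc$mul - prior$l_mu)^2) / v0 - 1 -
                     enc$lvl + log(v0))
    tibble::tibble(elbo = mean(recon - kl_z - kl_l), recon = mean(recon),
                   kl_z = mean(kl_z), kl_l = mean(kl_l))
  })
}

nb_draw_matrix <- function(mu, theta) {
  n <- nrow(mu)
  matrix(stats::rnbinom(length(mu), size = rep(theta, each = n),
                        mu = pmax(as.vector(mu), 1e-8)), n)
}

#' Generate synthetic cells by posterior sampling (replicate-and-stack)
#'
#' The input cells are replicated `ceiling(n_target / n_cells)` times; for
#' each copy, latents are drawn from the variational posterior
#' `q(z, l | x)` and counts from the NB likelihood; the first `n_target`
#' rows are returned. Generating more cells than the input therefore
#' reuses each original cell several times.
#'
#' @param fit An `"nbvae"` object.
#' @param cm A [count_matrix()] of cells to condition on.
#' @param n_target Number of synthetic cells (>= 1).
#' @param seed Integer seed.
#' @return A [count_matrix()] of `n_target` x `M` counts.
#' @export
vae_sample_posterior <- function(fit, cm, n_target, seed = 1L) {
  X <- unclass(cm)
  storage.mode(X) <- "double"
  if (!nrow(X)) stop("empty input count matrix", call. = FALSE)
  if (n_target < 1) stop("n_target must be >= 1", call. = FALSE)
  w <- fit$weights
  theta <- exp(w$log_theta)
  n_rep <- ceiling(n_target / nrow(X))
  out <- withr::with_seed(seed, {
    chunks <- vector("list", n_rep)
    enc <- nbvae_encode(w, X)
    for (r in seq_len(n_rep)) {
      Ez <- matrix(stats::rnorm(length(enc$muz)), nrow(X))
      El <- stats::rnorm(nrow(X))
      z <- enc$muz + exp(0.5 * enc$lvz) * Ez
      l <- enc$mul + exp(0.5 * enc$lvl) * El
      chunks[[r]] <- nb_draw_matrix(nbvae_decode(w, z, l)$mu, theta)
    }
    do.call(rbind, chunks)[seq_len(n_target), , drop = FALSE]
  })
  count_matrix(out, paste0("syn", seq_len(n_target)), fit$genes)
}

#' Generate synthetic cells by prior sampling
#'
#' Latents are drawn from the model prior -- `z ~ Normal(0, 1)` in each
#' latent dimension and log library size `l ~ Normal(l_mu, 1)` -- then
#' decoded and realized as NB counts. No original cell is accessed, so
#' samples can populate latent regions away from the training data.
#'
#' @param fit An `"nbvae"` object.
#' @param n_target Number of synthetic cells (>= 1).
#' @param seed Integer seed.
#' @return A [count_matrix()] of `n_target` x `M` counts.
#' @export
vae_sample_prior <- function(fit, n_target, seed = 1L) {
  if (n_target < 1) stop("n_target must be >= 1", call. = FALSE)
  w <- fit$weights
  theta <- exp(w$log_theta)
  out <- withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_target * fit$config$latent_dim), n_target)
    l <- stats::rnorm(n_target, fit$prior$l_mu, 1)
    nb_draw_matrix(nbvae_decode(w, z, l)$mu, theta)
  })
  count_matrix(out, paste0("syn", seq_len(n_target)), fit$genes)
}

#' Save / load an NB-VAE checkpoint
#'
#' @param fit An `"nbvae"` object.
#' @param path Output path (JSON).
#' @return `read_nbvae()` returns the restored `"nbvae"` object.
#' @export
write_nbvae <- function(fit, path) {
  payload <- list(format = "scpilot-nbvae", version = 1L,
                  genes = fit$genes, n_cells_trained = fit$n_cells_trained,
                  prior = fit$prior, config = unclass(fit$config),
                  weights = fit$weights)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nbvae
#' @export
read_nbvae <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "scpilot-nbvae")) {
    stop("not an NB-VAE checkpoint: ", path, call. = FALSE)
  }
  w <- j$weights
  for (nm in c("We", "Wmz", "Wvz", "wml", "wvl", "Wd", "Wp")) {
    w[[nm]] <- as.matrix(w[[nm]])
  }
  structure(list(weights = w, config = do.call(nbvae_config, j$config),
                 prior = j$prior, genes = j$genes,
                 n_cells_trained = j$n_cells_trained,
                 history = tibble::tibble()),
            class = "nbvae")
}
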