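test_that("parameter constructor enforces the feasibility invariants", {
  p <- tiny_params()
  expect_s3_class(p, "scdbm_params")
  expect_error(scdbm_params(c(0.1, -1), p$b1, p$b2, p$W1, p$W2, p$theta),
               "a <= -eps")
  expect_error(scdbm_params(p$a, p$b1, p$b2, abs(p$W1), p$W2, p$theta),
               "W1")
  expect_error(scdbm_params(p$a, p$b1, p$b2, p$W1, p$W2, c(-1, 2)),
               "theta")
})

test_that("apply_constraints clips into the feasible region and is idempotent", {
  p <- unclass(tiny_params())
  p$a[1] <- 0.3
  p$W1[1, 1] <- 0.7
  q <- apply_constraints(p)
  expect_equal(q$a[1], -1e-10)
  expect_equal(q$W1[1, 1], 0)
  expect_equal(q$W1[2, 1], -0.1)  # already-feasible entries untouched
  expect_identical(apply_constraints(q), q)
})

test_that("energy matches an independent term-by-term evaluation", {
  p <- tiny_params()
  expect_equal(scdbm_energy(c(0, 0), c(0, 0), c(0, 0), p), 0)
  zero <- scdbm_params(c(-1e-10, -1e-10), c(0, 0), c(0, 0),
                       matrix(0, 2, 2), matrix(0, 2, 2), c(1, 1))
  expect_equal(scdbm_energy(c(0, 0), c(0, 0), c(0, 0), zero), 0)
  # random small state, explicit scalar-loop oracle with log-gamma
  x <- c(4, 1); h1 <- c(1, 0); h2 <- c(0, 1)
  lchoose_term <- function(xm, tm) {
    lgamma(xm + tm) - lgamma(tm) - lgamma(xm + 1)
  }
  e <- 0
  for (m in 1:2) e <- e - p$a[m] * x[m] - lchoose_term(x[m], p$theta[m])
  for (k in 1:2) e <- e - p$b1[k] * h1[k]
  for (l in 1:2) e <- e - p$b2[l] * h2[l]
  for (m in 1:2) for (k in 1:2) e <- e - x[m] * p$W1[m, k] * h1[k]
  for (k in 1:2) for (l in 1:2) e <- e - h1[k] * p$W2[k, l] * h2[l]
  expect_equal(scdbm_energy(x, h1, h2, p), e)
  expect_error(scdbm_energy(c(1, 2, 3), h1, h2, p), "dimensions")
})

test_that("visible conditional follows the natural-parameter mean formula", {
  # a_hat = log(1/2), theta = 3 gives mu = 3 * (1/2) / (1/2) = 3
  p <- scdbm_params(a = rep(log(0.5), 2), b1 = 0, b2 = 0,
                    W1 = matrix(0, 2, 1), W2 = matrix(0, 1, 1),
                    theta = c(3, 3))
  expect_equal(visible_conditional(1, p)$mu, c(3, 3))
  # very negative natural parameter drives the mean to zero
  p2 <- scdbm_params(a = c(-30, -30), b1 = 0, b2 = 0,
                     W1 = matrix(0, 2, 1), W2 = matrix(0, 1, 1),
                     theta = c(3, 3))
  expect_lt(max(visible_conditional(1, p2)$mu), 1e-10)
  # h1 = 0 reduces to the bias
  p3 <- tiny_params()
  cond <- visible_conditional(c(0, 0), p3)
  expect_equal(cond$mu, p3$theta * exp(p3$a) / (1 - exp(p3$a)))
  # invariant violation is reported
  bad <- unclass(p3)
  bad$a[1] <- 0.2
  expect_error(visible_conditional(c(0, 0), bad), "valid region")
})

test_that("hidden samplers hit their Bernoulli rates", {
  p <- tiny_params()
  n <- 1e5
  # b-hat = 0 gives rate 1/2
  p0 <- scdbm_params(c(-1, -1), b1 = c(0, 0), b2 = c(0, 0),
                     W1 = matrix(0, 2, 2), W2 = matrix(0, 2, 2),
                     theta = c(1, 1))
  r <- withr::with_seed(21, mean(replicate(2000,
                                           sample_hidden1(c(3, 1), c(1, 0),
                                                          p0)[1])))
  expect_lt(abs(r - 0.5), 3 * sqrt(0.25 / 2000))
  # generic activation: empirical rate matches sigmoid(b1 + W1'x + W2 h2)
  x <- c(4, 2); h2 <- c(1, 0)
  act <- p$b1 + drop(t(p$W1) %*% x) + drop(p$W2 %*% h2)
  draws <- withr::with_seed(22,
                            t(replicate(n / 10, sample_hidden1(x, h2, p))))
  for (k in 1:2) {
    pk <- stats::plogis(act[k])
    expect_lt(abs(mean(draws[, k]) - pk),
              3 * sqrt(pk * (1 - pk) / (n / 10)))
  }
  act2 <- p$b2 + drop(t(p$W2) %*% c(1, 1))
  draws2 <- withr::with_seed(23,
                             t(replicate(n / 10, sample_hidden2(c(1, 1), p))))
  for (l in 1:2) {
    pl <- stats::plogis(act2[l])
    expect_lt(abs(mean(draws2[, l]) - pl),
              3 * sqrt(pl * (1 - pl) / (n / 10)))
  }
})

test_that("visible sampling reproduces NB moments including the Poisson limit", {
  n <- 1e5
  p <- scdbm_params(a = rep(log(0.5), 1), b1 = 0, b2 = 0,
                    W1 = matrix(0, 1, 1), W2 = matrix(0, 1, 1), theta = 3)
  draws <- withr::with_seed(24, vapply(seq_len(n / 20), function(i) {
    sample_visible(1, p)
  }, numeric(1)))
  expect_lt(abs(mean(draws) - 3), 3 * sqrt(6 / (n / 20)))
  expect_lt(abs(stats::var(draws) - 6), 0.4)
  # large theta: variance approaches the mean
  ptheta <- scdbm_params(a = log(3 / (3 + 1e6)), b1 = 0, b2 = 0,
                         W1 = matrix(0, 1, 1), W2 = matrix(0, 1, 1),
                         theta = 1e6)
  d2 <- withr::with_seed(25, vapply(seq_len(5000), function(i) {
    sample_visible(0, ptheta)
  }, numeric(1)))
  expect_lt(abs(stats::var(d2) / mean(d2) - 1), 0.1)
})

test_that("exact enumeration agrees with a brute-force oracle over hidden configs", {
  p <- tiny_params()
  mom <- scpilot:::scdbm_exact_moments(p)
  # independent oracle: loop over all 16 (h1, h2) pairs
  configs1 <- expand.grid(0:1, 0:1)
  configs2 <- expand.grid(0:1, 0:1)
  w <- matrix(0, 4, 4)
  for (i in 1:4) {
    h1 <- as.numeric(configs1[i, ])
    ahat <- p$a + drop(p$W1 %*% h1)
    lz <- -sum(p$theta * log(1 - exp(ahat)))
    for (j in 1:4) {
      h2 <- as.numeric(configs2[j, ])
      w[i, j] <- exp(sum(p$b1 * h1) + sum(p$b2 * h2) +
                       drop(h1 %*% p$W2 %*% h2) + lz)
    }
  }
  w <- w / sum(w)
  expect_equal(as.vector(mom$P), as.vector(w), tolerance = 1e-12)
  Eh1 <- colSums(as.matrix(configs1) * rowSums(w))
  expect_equal(unname(mom$Eh1), unname(Eh1), tolerance = 1e-12)
  # E[x] = sum over h1 configs of mu_hat(h1) weighted by their mass
  Ex <- c(0, 0)
  for (i in 1:4) {
    h1 <- as.numeric(configs1[i, ])
    ahat <- p$a + drop(p$W1 %*% h1)
    Ex <- Ex + rowSums(w)[i] * p$theta * exp(ahat) / (1 - exp(ahat))
  }
  expect_equal(unname(mom$Ex), unname(Ex), tolerance = 1e-12)
})

test_that("analytic model moments equal finite differences of the exact log-partition", {
  p <- tiny_params()
  logZ <- function(q) {
    H1 <- as.matrix(expand.grid(0:1, 0:1))
    H2 <- as.matrix(expand.grid(0:1, 0:1))
    tot <- -Inf
    for (i in 1:4) {
      h1 <- H1[i, ]
      ahat <- q$a + drop(q$W1 %*% h1)
      lz <- -sum(q$theta * log(1 - exp(ahat)))
      for (j in 1:4) {
        h2 <- H2[j, ]
        v <- sum(q$b1 * h1) + sum(q$b2 * h2) + drop(h1 %*% q$W2 %*% h2) + lz
        tot <- max(tot, v) + log1p(exp(min(tot, v) - max(tot, v)))
      }
    }
    tot
  }
  mom <- scpilot:::scdbm_exact_moments(p)
  h <- 1e-6
  for (k in 1:2) {
    q1 <- unclass(p); q1$b1[k] <- q1$b1[k] + h
    q2 <- unclass(p); q2$b1[k] <- q2$b1[k] - h
    expect_equal((logZ(q1) - logZ(q2)) / (2 * h), mom$Eh1[k],
                 tolerance = 1e-5)
  }
  for (m in 1:2) {
    q1 <- unclass(p); q1$a[m] <- q1$a[m] + h
    q2 <- unclass(p); q2$a[m] <- q2$a[m] - h
    expect_equal((logZ(q1) - logZ(q2)) / (2 * h), mom$Ex[m],
                 tolerance = 1e-4)
  }
})

test_that("exact per-cell posterior matches enumeration over hidden states", {
  p <- tiny_params()
  X <- matrix(c(5, 0, 2, 7), 2, 2)
  ps <- scpilot:::scdbm_exact_posterior(X, p)
  for (n in 1:2) {
    x <- X[n, ]
    w1 <- numeric(4)
    H1 <- as.matrix(expand.grid(0:1, 0:1))
    H2 <- as.matrix(expand.grid(0:1, 0:1))
    for (i in 1:4) {
      for (j in 1:4) {
        h1 <- H1[i, ]; h2 <- H2[j, ]
        w1[i] <- w1[i] + exp(sum(p$b1 * h1) + sum(p$b2 * h2) +
                               sum(x * drop(p$W1 %*% h1)) +
                               drop(h1 %*% p$W2 %*% h2))
      }
    }
    expect_equal(unname(ps$Q1[n, ]), unname(w1 / sum(w1)),
                 tolerance = 1e-10)
  }
})

test_that("training with zero epochs returns the constrained initialization", {
  sp <- fx_single_pop()
  fit <- train_scdbm(sp$counts, scdbm_config(epochs = 0,
                                             pretrain_epochs = 0, seed = 2))
  p <- fit$params
  expect_true(all(p$a <= -1e-10))
  expect_true(all(p$W1 <= 0))
  expect_true(all(p$theta > 0))
  expect_identical(nrow(fit$history), 0L)
  # method-of-moments dispersion on a homogeneous gene is near the truth
  expect_gt(stats::median(p$theta), 1)
  expect_lt(stats::median(p$theta), 4)
})

test_that("training keeps constraints and reconstruction error does not degrade", {
  fit <- train_scdbm(fx_single_pop()$counts,
                     scdbm_config(epochs = 15, seed = 4))
  p <- fit$params
  expect_true(all(p$a <= -1e-10))
  expect_true(all(p$W1 <= 0))
  h <- fit$history$recon_moment_error
  expect_lte(mean(utils::tail(h, 5)), mean(utils::head(h, 5)) + 0.02)
  # moment recovery: generated means within 20% of training means
  syn <- scdbm_generate(fit, 4000, seed = 5)
  mo <- colMeans(fx_single_pop()$counts)
  expect_lt(max(abs(colMeans(syn) - mo) / pmax(mo, 0.5)), 0.2)
})

test_that("generation is deterministic, shape-correct, and respects the marginal", {
  p <- tiny_params()
  g0 <- scdbm_generate(p, 0, seed = 1)
  expect_identical(dim(g0), c(0L, 2L))
  g1 <- scdbm_generate(p, 200, seed = 9)
  g2 <- scdbm_generate(p, 200, seed = 9)
  expect_identical(unclass(g1), unclass(g2))
  g3 <- scdbm_generate(p, 200, seed = 10)
  expect_false(identical(unclass(g1), unclass(g3)))
  expect_error(scdbm_generate(p, 10, gibbs_steps = 0), "gibbs_steps")
  # zero-weight model: per-gene mean matches the bias-only NB mean
  pz <- scdbm_params(a = c(log(3 / 5), log(1 / 3)), b1 = c(0.4, -0.3),
                     b2 = c(0, 0), W1 = matrix(0, 2, 2),
                     W2 = matrix(0, 2, 2), theta = c(2, 2))
  mu <- pz$theta * exp(pz$a) / (1 - exp(pz$a))
  syn <- scdbm_generate(pz, 20000, burn_in = 5, seed = 11)
  se <- sqrt((mu + mu^2 / pz$theta) / 20000)
  expect_true(all(abs(colMeans(syn) - mu) < 4 * se))
})

test_that("checkpoints round trip through JSON and reproduce generation", {
  fit <- fx_scdbm_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_scdbm(fit, path)
  back <- read_scdbm(path)
  expect_equal(back$params$a, fit$params$a)
  expect_equal(back$params$W1, fit$params$W1, ignore_attr = TRUE)
  expect_equal(back$params$theta, fit$params$theta)
  expect_identical(unclass(scdbm_generate(back, 50, seed = 3)),
                   unclass(scdbm_generate(fit, 50, seed = 3)))
  other <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", other)
  expect_error(read_scdbm(other), "not an scDBM checkpoint")
})

test_that("chain-based negative phases remain available for larger latent spaces", {
  sp <- fx_single_pop()
  for (npz in c("cd", "pcd")) {
    fit <- train_scdbm(sp$counts,
                       scdbm_config(epochs = 5, pretrain_epochs = 2,
                                    negative_phase = npz, n_chains = 50,
                                    calibrate_prior = FALSE, seed = 6))
    expect_true(all(fit$params$W1 <= 0))
    expect_true(all(is.finite(fit$params$a)))
  }
})
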