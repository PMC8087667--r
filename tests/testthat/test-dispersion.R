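test_that("nb_logpmf matches closed forms and normalizes", {
  # at v = 0 and mu = theta the log pmf is theta * log(1/2)
  expect_equal(nb_logpmf(0, mu = 3, theta = 3), 3 * log(0.5))
  expect_equal(nb_logpmf(0, mu = 7, theta = 2), 2 * log(2 / 9))
  # total mass over the support
  for (mu in c(1, 5, 50)) {
    for (th in c(0.5, 2, 10)) {
      expect_equal(sum(exp(nb_logpmf(0:10000, mu, th))), 1,
                   tolerance = 1e-8)
    }
  }
  # Poisson limit as theta -> infinity
  expect_equal(nb_logpmf(0:5, mu = 2, theta = 1e6),
               stats::dpois(0:5, 2, log = TRUE), tolerance = 1e-3)
  expect_error(nb_logpmf(0:2, -1, 2), "mu")
  expect_error(nb_logpmf(c(0, 1.5), 2, 2), "integers")
})

test_that("gamma-Poisson mixture draws match the NB pmf", {
  n <- 1e5
  draws <- withr::with_seed(11, rnb(n, mu = 4, theta = 1.5,
                                    method = "gamma_poisson"))
  for (v in 0:6) {
    p <- exp(nb_logpmf(v, 4, 1.5))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws == v) - p), 3 * se + 1e-4)
  }
  # and the two sampling routes agree in distribution (chi-square)
  d2 <- withr::with_seed(12, rnb(n, mu = 4, theta = 1.5, method = "nb"))
  brk <- c(seq(-0.5, 14.5, 1), Inf)
  tab <- rbind(table(cut(draws, brk)), table(cut(d2, brk)))
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)
})

test_that("score and information match finite differences of the log-likelihood", {
  cases <- list(list(mu = 5, theta = 2, n = 200, seed = 1),
                list(mu = 1.3, theta = 0.6, n = 150, seed = 2),
                list(mu = 20, theta = 8, n = 100, seed = 3))
  for (cs in cases) {
    x <- withr::with_seed(cs$seed, stats::rnbinom(cs$n, size = cs$theta,
                                                  mu = cs$mu))
    mu <- withr::with_seed(cs$seed + 10, stats::runif(cs$n, 0.5, 2) * cs$mu)
    ll <- function(t) sum(nb_logpmf(x, mu, t))
    h <- 1e-5 * cs$theta
    fd1 <- (ll(cs$theta + h) - ll(cs$theta - h)) / (2 * h)
    expect_equal(nb_score(cs$theta, x, mu), fd1, tolerance = 1e-6)
    # wider step for the second difference: the tiny-h quotient loses
    # precision to cancellation before the 1e-5 comparison is meaningful
    h2 <- 1e-3 * cs$theta
    fd2 <- -(ll(cs$theta + h2) - 2 * ll(cs$theta) + ll(cs$theta - h2)) / h2^2
    expect_equal(nb_fisher_info(cs$theta, x, mu), fd2, tolerance = 1e-5)
  }
})

test_that("information is additive over replicated data and positive at the MLE", {
  x <- withr::with_seed(4, stats::rnbinom(300, size = 2, mu = 5))
  expect_equal(nb_fisher_info(2, c(x, x), 5), 2 * nb_fisher_info(2, x, 5))
  mle <- stats::optimize(function(t) sum(nb_logpmf(x, 5, t)), c(0.1, 50),
                         maximum = TRUE, tol = 1e-8)$maximum
  expect_lt(abs(nb_score(mle, x, 5)), 1e-2)
  expect_gt(nb_fisher_info(mle, x, 5), 0)
})

test_that("one scoring update is near-identity at the MLE and the penalty pushes small theta up", {
  x <- withr::with_seed(5, stats::rnbinom(500, size = 2, mu = 5))
  mle <- stats::optimize(function(t) sum(nb_logpmf(x, 5, t)), c(0.1, 50),
                         maximum = TRUE, tol = 1e-10)$maximum
  upd <- fisher_scoring_update(mle, x, 5, lambda_reg = 0)
  expect_lt(abs(upd - mle) / mle, 1e-4)
  # at the unpenalized optimum the score vanishes, so any positive
  # penalty moves the iterate strictly upward (shrinkage toward larger
  # theta, i.e. less estimated heterogeneity)
  expect_gt(fisher_scoring_update(mle, x, 5, lambda_reg = 50), mle)
  # and the damping denominator keeps the regularized step finite from
  # a small starting value
  up50 <- fisher_scoring_update(0.3, x, 5, lambda_reg = 50)
  expect_gt(up50, 0.3)
  expect_true(is.finite(up50))
})

test_that("estimate_theta recovers the MLE and is monotone in the penalty", {
  x <- withr::with_seed(6, stats::rnbinom(2000, size = 2, mu = 5))
  est0 <- estimate_theta(x, 5, fisher_scoring_config(lambda_reg = 0))
  expect_true(attr(est0, "converged"))
  expect_gt(est0, 1.7)
  expect_lt(est0, 2.3)
  # brute-force oracle: log-spaced grid bracket + golden-section refinement
  grid <- exp(seq(log(0.05), log(50), length.out = 200))
  ll <- vapply(grid, function(t) sum(nb_logpmf(x, 5, t)), numeric(1))
  i <- which.max(ll)
  oracle <- stats::optimize(function(t) sum(nb_logpmf(x, 5, t)),
                            c(grid[max(1, i - 1)],
                              grid[min(length(grid), i + 1)]),
                            maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(est0 - oracle) / oracle, 0.01)
  prev <- as.numeric(est0)
  for (lam in c(1, 10, 100)) {
    cur <- as.numeric(estimate_theta(x, 5,
                                     fisher_scoring_config(lambda_reg = lam)))
    expect_gte(cur, prev - 1e-8)
    prev <- cur
  }
})

test_that("degenerate all-zero genes hit the upper bound with a warning", {
  expect_warning(est <- estimate_theta(rep(0L, 50), 1,
                                       fisher_scoring_config()),
                 "all-zero")
  expect_equal(as.numeric(est), 1000)
  expect_false(attr(est, "converged"))
})

test_that("the unpenalized estimator is nearly unbiased across dispersion regimes", {
  for (th in c(0.5, 2, 10)) {
    ests <- vapply(1:50, function(r) {
      x <- withr::with_seed(1000 * th + r,
                            stats::rnbinom(5000, size = th, mu = 8))
      as.numeric(estimate_theta(x, 8, fisher_scoring_config(lambda_reg = 0)))
    }, numeric(1))
    expect_lt(abs(mean(ests) - th) / th, 0.05)
  }
})
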