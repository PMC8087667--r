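# Shared fixtures, memoized so expensive objects (trained models, reference
# clusterings) are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# canonical two-population fixture (study conditions: n = 2000, 50 genes,
# fold change 8 on 10 markers)
fx_mixture <- function() memo("fx_mixture", two_population_fixture(seed = 3))

fx_reference <- function() {
  memo("fx_reference", reference_clustering(fx_mixture()$counts, seed = 1))
}

fx_pilot384 <- function() {
  memo("fx_pilot384",
       subsample_plates(fx_mixture()$counts, 1, 384, seed = 11))
}

fx_scdbm_fit <- function() {
  memo("fx_scdbm_fit", train_scdbm(fx_pilot384(), scdbm_config(seed = 5)))
}

fx_scdbm_syn <- function() {
  memo("fx_scdbm_syn", scdbm_generate(fx_scdbm_fit(), 2000, seed = 7))
}

# small single-population fixture for moment-recovery checks
fx_single_pop <- function() {
  memo("fx_single_pop", {
    means <- matrix(withr::with_seed(8, stats::rlnorm(30, log(3), 0.5)), 1)
    simulate_nb_mixture(mixture_spec(400, 30, means, seed = 9))
  })
}

random_counts <- function(n, g, mu = 5, theta = 2, seed = 1) {
  withr::with_seed(seed, {
    count_matrix(matrix(stats::rnbinom(n * g, size = theta, mu = mu), n, g),
                 paste0("c", seq_len(n)), paste0("g", seq_len(g)))
  })
}

# tiny scDBM parameter set used across sampler tests
tiny_params <- function() {
  scdbm_params(a = c(-0.8, -1.2), b1 = c(0.3, -0.2), b2 = c(0.1, -0.1),
               W1 = matrix(c(-0.25, -0.1, -0.05, -0.3), 2, 2),
               W2 = matrix(c(0.5, -0.4, 0.3, 0.2), 2, 2),
               theta = c(2, 3))
}
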