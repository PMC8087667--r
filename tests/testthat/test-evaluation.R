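test_that("reference clustering recovers the two planted populations", {
  fx <- fx_mixture()
  rc <- fx_reference()
  expect_identical(rc$n_clusters, 2L)
  expect_gte(adjusted_rand(rc$labels$label, fx$labels$label), 0.95)
  # deterministic under a fixed seed
  rc2 <- reference_clustering(fx$counts, seed = 1)
  expect_identical(rc$labels$label, rc2$labels$label)
  expect_error(reference_clustering(random_counts(10, 5), k = 15),
               "fewer cells")
})

test_that("user-supplied coordinates and labels pass through verbatim", {
  coords <- matrix(stats::rnorm(20), 10, 2)
  labs <- labeled_cells(paste0("c", 1:10), rep(0:1, 5))
  rc <- reference_clustering(random_counts(10, 5), coords = coords,
                             labels = labs)
  expect_identical(rc$coords, coords)
  expect_identical(rc$labels, labs)
  expect_identical(rc$provider, "user")
  expect_error(transfer_labels(rc, random_counts(3, 5)), "projection")
})

test_that("label transfer is self-consistent and matches a brute-force oracle", {
  rc <- fx_reference()
  fx <- fx_mixture()
  # the reference cells map to themselves
  self <- transfer_labels(rc, fx$counts)
  expect_identical(self$label, rc$labels$label)
  # a query placed exactly on a reference point takes its label
  one <- transfer_labels(rc, count_matrix(matrix(0L, 1, 50, dimnames =
                                                   list("q", colnames(fx$counts)))),
                         query_coords = rc$coords[17, , drop = FALSE])
  expect_identical(one$label, rc$labels$label[17])
  # O(n^2) oracle on 200 random projected query cells
  qc <- withr::with_seed(31, matrix(stats::rnorm(400, sd = 5), 200, 2))
  got <- transfer_labels(rc, count_matrix(matrix(0L, 200, 50, dimnames =
                                                   list(paste0("q", 1:200),
                                                        colnames(fx$counts)))),
                         query_coords = qc)
  oracle <- vapply(seq_len(200), function(i) {
    d <- sqrt(rowSums(sweep(rc$coords, 2, qc[i, ])^2))
    rc$labels$label[which.min(d)]
  }, integer(1))
  expect_identical(got$label, oracle)
})

test_that("Davies-Bouldin follows the printed formulas in both variants", {
  # two singleton clusters at distance 1: zero dispersion, index 0
  coords <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(davies_bouldin(coords, c(0, 1), "classical"), 0)
  expect_equal(davies_bouldin(coords, c(0, 1), "as_printed"), 0)
  # 2 clusters of 2 points on a line: hand computation gives 0.1 / 0
  line <- cbind(c(0, 1, 10, 11), 0)
  labs <- c(0, 0, 1, 1)
  expect_equal(davies_bouldin(line, labs, "classical"), 0.1)
  expect_equal(davies_bouldin(line, labs, "as_printed"), 0)
  # label permutation invariance
  expect_equal(davies_bouldin(line, 1 - labs, "classical"), 0.1)
  # shrinking within-cluster dispersion at fixed centroids lowers the index
  tight <- cbind(c(0.25, 0.75, 10.25, 10.75), 0)
  expect_lt(davies_bouldin(tight, labs, "classical"),
            davies_bouldin(line, labs, "classical"))
  expect_error(davies_bouldin(cbind(c(0, 0, 1, 1), 0), c(0, 1, 0, 1)),
               "coincident")
  expect_error(davies_bouldin(line, rep(0, 4)), "at least 2")
})

test_that("adjusted Rand index reproduces closed-form values and chance level", {
  expect_equal(adjusted_rand(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # contingency table [[1,1],[1,1]] on 4 items
  expect_equal(adjusted_rand(c(0, 0, 1, 1), c(0, 1, 0, 1)), -1 / 2)
  # symmetry
  a <- withr::with_seed(5, sample(0:2, 60, replace = TRUE))
  b <- withr::with_seed(6, sample(0:3, 60, replace = TRUE))
  expect_equal(adjusted_rand(a, b), adjusted_rand(b, a))
  # chance correction: independent shuffles average to ~0
  m <- withr::with_seed(7, mean(vapply(1:200, function(i) {
    adjusted_rand(a, sample(b))
  }, numeric(1))))
  expect_lt(abs(m), 0.05)
  expect_error(adjusted_rand(a, b[1:10]), "length")
})

test_that("adjusted Rand agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    a <- withr::with_seed(s, sample(0:3, 100, replace = TRUE))
    b <- withr::with_seed(s + 50, sample(0:2, 100, replace = TRUE))
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cluster proportion deviation counts absent clusters as zero", {
  expect_equal(cluster_proportion_mad(rep(0:1, c(10, 5)),
                                      rep(0:1, c(10, 5))), 0)
  expect_equal(cluster_proportion_mad(rep(0:1, c(10, 5)),
                                      rep(0:1, c(5, 10))), 5)
  expect_equal(cluster_proportion_mad(rep(0:1, c(10, 6)), rep(0L, 16)), 6)
  expect_error(cluster_proportion_mad(integer(0), 1L), "empty")
})

test_that("per-gene statistic deviations behave as marginal summaries", {
  cm <- random_counts(40, 8)
  for (st in c("median", "iqr", "cv", "zero_fraction")) {
    expect_equal(as.numeric(gene_stat_mad(cm, cm, st)), 0)
  }
  # worked example: zero fractions 0.5 vs 0.25 on one gene
  o <- count_matrix(matrix(c(0L, 0L, 2L, 2L), 4, 1), paste0("c", 1:4), "g")
  s <- count_matrix(matrix(c(0L, 2L, 2L, 2L), 4, 1), paste0("c", 1:4), "g")
  expect_equal(gene_stat_mad(o, s, "zero_fraction"), 0.25)
  # cell order is irrelevant
  perm <- count_matrix(unclass(cm)[sample(40), ], paste0("p", 1:40),
                       colnames(cm))
  expect_equal(gene_stat_mad(cm, perm, "median"), 0)
  expect_equal(as.numeric(gene_stat_mad(cm, perm, "cv")), 0)
  bad <- count_matrix(unclass(cm), rownames(cm), paste0("x", 1:8))
  expect_error(gene_stat_mad(cm, bad, "median"), "gene sets")
})

test_that("zero-preservation check flags refilled zeros and only those", {
  orig <- random_counts(200, 10, mu = 8)
  corr <- add_artificial_zeros(orig, 0.3, seed = 2)
  same <- zero_preservation_check(orig, corr, corr)
  expect_equal(same$mean_abs_gap, 0)
  expect_length(same$flagged, 0)
  # a generator that reproduces the pre-corruption data imputes zeros
  refill <- zero_preservation_check(orig, corr, orig, margin = 0.1)
  inflated <- colMeans(unclass(corr) == 0) - colMeans(unclass(orig) == 0) > 0.1
  expect_setequal(refill$flagged, colnames(orig)[inflated])
  expect_error(zero_preservation_check(orig, corr,
                                       random_counts(10, 3)), "gene sets")
})

test_that("evaluate_synthetic assembles a one-row tidy report", {
  rc <- fx_reference()
  fx <- fx_mixture()
  syn <- fx_scdbm_syn()
  rep <- evaluate_synthetic(rc, fx$counts, syn, seed = 2)
  expect_s3_class(rep, "tbl_df")
  expect_identical(nrow(rep), 1L)
  expect_gte(rep$dbi, 0)
  expect_true(rep$ari >= -1 && rep$ari <= 1)
  expect_identical(rep$n_cells_generated, 2000L)
  expect_true(all(c("mad_median", "mad_iqr", "mad_cv",
                    "mad_zero_fraction") %in% names(rep)))
})
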