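#' Specification of a negative-binomial mixture of cell populations
#'
#' Ground-truth generator emulating clustered scRNA-seq counts: each cell
#' belongs to a cluster drawn from `proportions`; its counts are NB with
#' mean `means[cluster, gene] * library factor` and per-gene inverse
#' dispersion `theta`; library factors are log-normal; optionally a
#' uniformly random fraction of entries is zeroed afterwards (excess
#' zeros).
#'
#' @param n_cells,n_genes Dimensions of the simulated matrix.
#' @param means Positive `n_clusters x n_genes` matrix of cluster mean
#'   expression.
#' @param proportions Cluster mixing proportions (must sum to 1).
#' @param theta Per-gene inverse dispersion (scalar recycled or length
#'   `n_genes`).
#' @param libsize_sdlog Log-normal sd of the per-cell library factor
#'   (meanlog 0).
#' @param extra_zero_fraction Fraction of entries zeroed after sampling.
#' @param seed Integer seed.
#' @return A list of class `"mixture_spec"`.
#' @export
mixture_spec <- function(n_cells, n_genes, means,
                         proportions = rep(1 / nrow(means), nrow(means)),
                         theta = 2, libsize_sdlog = 0.2,
                         extra_zero_fraction = 0, seed = 1L) {
  means <- as.matrix(means)
  if (ncol(means) != n_genes) stop("means must be n_clusters x n_genes",
                                   call. = FALSE)
  if (any(means <= 0)) stop("means must be positive", call. = FALSE)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be a simplex (non-negative, sum 1)",
         call. = FALSE)
  }
  theta <- rep_len(theta, n_genes)
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  stopifnot(extra_zero_fraction >= 0, extra_zero_fraction <= 1)
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes), means = means,
                 proportions = proportions, theta = theta,
                 libsize_sdlog = libsize_sdlog,
                 extra_zero_fraction = extra_zero_fraction,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Simulate clustered NB counts from a mixture specification
#'
#' @param spec A [mixture_spec()].
#' @return A list with `counts` ([count_matrix()]) and `labels`
#'   ([labeled_cells()], 0-based cluster ids).
#' @export
simulate_nb_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    G <- spec$n_genes
    cl <- sample.int(nrow(spec$means), n, replace = TRUE,
                     prob = spec$proportions)
    lib <- stats::rlnorm(n, 0, spec$libsize_sdlog)
    Mu <- spec$means[cl, , drop = FALSE] * lib
    X <- matrix(stats::rnbinom(n * G, size = rep(spec$theta, each = n),
                               mu = as.vector(Mu)), n, G)
    if (spec$extra_zero_fraction > 0) {
      zero <- stats::runif(n * G) < spec$extra_zero_fraction
      X[zero] <- 0L
    }
    list(counts = count_matrix(X, paste0("cell", seq_len(n)),
                               paste0("gene", seq_len(G))),
         labels = labeled_cells(paste0("cell", seq_len(n)), cl - 1L, contiguous = TRUE))
  })
}

#' Canonical two-population fixture
#'
#' A two-cluster NB mixture with equal proportions: `n_markers` marker
#' genes at `fold_change` elevated mean, half up in each population, on a
#' shared log-normal baseline; per-gene inverse dispersion 2 and mild
#' library-size variation, typical of UMI data after gene filtering.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_markers Number of marker genes (split between the clusters).
#' @param fold_change Marker mean fold change between populations.
#' @param theta Per-gene inverse dispersion.
#' @param seed Integer seed (drives both the mean construction and the
#'   count draw).
#' @return As [simulate_nb_mixture()], with an extra element `spec`.
#' @export
two_population_fixture <- function(n_cells = 2000L, n_genes = 50L,
                                   n_markers = 10L, fold_change = 8,
                                   theta = 2, seed = 1L) {
  base <- withr::with_seed(seed + 1L,
                           stats::rlnorm(n_genes, log(2), 0.5))
  means <- rbind(base, base)
  half <- n_markers %/% 2
  up_a <- seq_len(half)
  up_b <- seq(half + 1, n_markers)
  means[1, up_a] <- base[up_a] * fold_change
  means[2, up_b] <- base[up_b] * fold_change
  spec <- mixture_spec(n_cells, n_genes, means,
                       proportions = c(0.5, 0.5), theta = theta,
                       libsize_sdlog = 0.2, seed = seed)
  out <- simulate_nb_mixture(spec)
  out$spec <- spec
  out
}

#' Negative-binomial noise baseline generator
#'
#' Training-free reference: per replicate and cell, a gamma variate with
#' scale ~ Uniform(0, 5) and shape ~ Uniform(0, 10) is drawn and used as
#' the rate of Poisson noise added to that cell's pilot counts (one rate
#' per cell, reused across genes; `per_gene = TRUE` draws a fresh rate per
#' gene instead). Noisy replicates of the pilot are stacked until
#' `target_n` cells are reached (e.g. ten replicates to take a 384-cell
#' pilot to 3840 cells), then truncated. Bounds the effect of pure
#' sampling bias: it preserves the pilot's cells exactly, plus noise.
#'
#' @param pilot A [count_matrix()] of pilot cells.
#' @param target_n Number of cells to produce (>= pilot size).
#' @param seed Integer seed.
#' @param per_gene Draw a separate gamma rate for every gene of a cell.
#' @return A [count_matrix()] of `target_n` cells.
#' @export
noise_baseline <- function(pilot, target_n, seed = 1L, per_gene = FALSE) {
  n <- nrow(pilot)
  G <- ncol(pilot)
  if (target_n < n) {
    stop("target_n (", target_n, ") is smaller than the pilot size (", n,
         ")", call. = FALSE)
  }
  n_rep <- ceiling(target_n / n)
  X <- unclass(pilot)
  out <- withr::with_seed(seed, {
    chunks <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      scale <- stats::runif(n, 0, 5)
      shape <- stats::runif(n, 0, 10)
      if (per_gene) {
        rate <- matrix(stats::rgamma(n * G, shape = rep(shape, G),
                                     scale = rep(scale, G)), n, G)
        noise <- matrix(stats::rpois(n * G, as.vector(rate)), n, G)
      } else {
        rate <- stats::rgamma(n, shape = shape, scale = scale)
        noise <- matrix(stats::rpois(n * G, rep(rate, G)), n, G)
      }
      chunks[[r]] <- X + noise
    }
    do.call(rbind, chunks)[seq_len(target_n), , drop = FALSE]
  })
  count_matrix(out, paste0("syn", seq_len(target_n)), colnames(pilot))
}

#' Set a random fraction of all matrix entries to zero
#'
#' Emulates extra technical dropout: a uniformly random `fraction` of all
#' entries (whether currently zero or not) is set to zero.
#'
#' @param cm A [count_matrix()].
#' @param fraction Fraction of entries to zero, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted [count_matrix()].
#' @export
add_artificial_zeros <- function(cm, fraction = 0.2, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(cm)
  X <- unclass(cm)
  zero <- withr::with_seed(seed, stats::runif(length(X)) < fraction)
  X[zero] <- 0L
  count_matrix(X, rownames(cm), colnames(cm))
}
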