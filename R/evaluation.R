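#' Reference clustering of a count matrix
#'
#' The package's stand-in for a typical analysis workflow: log1p
#' median-library normalization, PCA, a 2-d embedding, and Louvain
#' community detection on a k-nearest-neighbour graph built in PC space.
#' The result carries a projection function so query (synthetic) cells can
#' be placed into the same embedding space. User-supplied coordinates and
#' labels can be passed through verbatim instead, so outputs of external
#' toolchains can be dropped in.
#'
#' @param cm A [count_matrix()].
#' @param n_pcs Number of principal components for the graph (capped at
#'   the data rank).
#' @param k Neighbours for the kNN graph.
#' @param resolution Louvain resolution parameter.
#' @param embedding `"pca"` (first two PCs; deterministic, the default) or
#'   `"umap"` (requires the uwot package).
#' @param coords,labels Optional user-supplied embedding coordinates
#'   (matrix, rows aligned with cells) and label table
#'   ([labeled_cells()]); when both are given they are returned unchanged
#'   and no clustering is run.
#' @param seed Integer seed.
#' @return An object of class `"ref_clustering"` with elements `coords`
#'   (n x 2), `labels` (tibble `cell_id`, `label`), `n_clusters`, and
#'   `project(counts)` mapping query counts into embedding space.
#' @export
reference_clustering <- function(cm, n_pcs = 10L, k = 15L, resolution = 0.25,
                                 embedding = c("pca", "umap"),
                                 coords = NULL, labels = NULL, seed = 1L) {
  embedding <- match.arg(embedding)
  if (!is.null(coords) && !is.null(labels)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == nrow(labels))
    return(structure(list(coords = coords, labels = labels,
                          n_clusters = length(unique(labels$label)),
                          project = NULL, provider = "user"),
                     class = "ref_clustering"))
  }
  if (!nrow(cm)) stop("empty count matrix", call. = FALSE)
  if (nrow(cm) <= k) {
    stop("fewer cells (", nrow(cm), ") than neighbours parameter k = ", k,
         call. = FALSE)
  }
  lib_target <- stats::median(rowSums(cm))
  norm <- normalize_log1p(cm, target = lib_target)
  centers <- colMeans(norm)
  n_pcs <- min(n_pcs, nrow(norm) - 1L, ncol(norm))
  pca <- stats::prcomp(norm, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pca$x

  labels_int <- withr::with_seed(seed, {
    nn <- knn_index(scores, k)
    g <- igraph::graph_from_edgelist(
      cbind(rep(seq_len(nrow(scores)), each = k), as.vector(t(nn))),
      directed = FALSE)
    g <- igraph::simplify(g)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(comm)
  })
  # relabel 0-based, largest cluster first, for determinism
  ord <- order(tabulate(labels_int), decreasing = TRUE)
  remap <- integer(max(labels_int))
  remap[ord] <- seq_along(ord) - 1L
  labels_int <- remap[labels_int]

  if (embedding == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("embedding = \"umap\" requires the uwot package", call. = FALSE)
    }
    um <- withr::with_seed(seed, uwot::umap(scores, n_neighbors = k,
                                            ret_model = TRUE))
    coords <- um$embedding
    project <- function(query) {
      qn <- normalize_log1p(query, target = lib_target)
      qs <- sweep(qn, 2, centers) %*% pca$rotation
      uwot::umap_transform(qs, um)
    }
  } else {
    coords <- scores[, 1:2, drop = FALSE]
    project <- function(query) {
      qn <- normalize_log1p(query, target = lib_target)
      qs <- sweep(qn, 2, centers) %*% pca$rotation
      qs[, 1:2, drop = FALSE]
    }
  }
  structure(list(coords = coords,
                 labels = labeled_cells(rownames(cm), labels_int, contiguous = TRUE),
                 n_clusters = length(unique(labels_int)),
                 project = project, provider = embedding),
            class = "ref_clustering")
}

#' @export
print.ref_clustering <- function(x, ...) {
  cat("<ref_clustering>", nrow(x$coords), "cells,", x$n_clusters,
      "clusters (provider:", paste0(x$provider, ")"), "\n")
  invisible(x)
}

# k nearest neighbours (excluding self) by Euclidean distance; returns an
# n x k index matrix
knn_index <- function(X, k) {
  d2 <- cross_dist2(X, X)
  diag(d2) <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

# squared Euclidean cross-distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
}

#' Transfer reference labels to query cells by nearest neighbour
#'
#' Each query cell is projected into the reference embedding space and
#' assigned the cluster label of its nearest reference cell by Euclidean
#' distance; ties resolve to the lowest reference index.
#'
#' @param ref A `"ref_clustering"` (must carry a projection unless
#'   `query_coords` is supplied).
#' @param query_counts A [count_matrix()] over the reference's genes.
#' @param query_coords Optional pre-projected query coordinates, bypassing
#'   the reference's projection function.
#' @return A [labeled_cells()] tibble for the query cells.
#' @export
transfer_labels <- function(ref, query_counts, query_coords = NULL) {
  if (is.null(query_coords)) {
    if (is.null(ref$project)) {
      stop("reference has no projection (user-supplied clustering); ",
           "pass query_coords", call. = FALSE)
    }
    query_coords <- tryCatch(ref$project(query_counts), error = function(e) {
      stop("projection of query cells failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  d2 <- cross_dist2(as.matrix(query_coords), ref$coords)
  nn <- apply(d2, 1, which.min)  # which.min takes the first (lowest) index
  labeled_cells(rownames(query_counts), ref$labels$label[nn])
}

#' Davies-Bouldin index
#'
#' Cluster compactness vs. separation: with per-cluster dispersion
#' `S_k = sqrt(mean of squared distances to the centroid)` and centroid
#' distances `M_ij`, the index is the mean over clusters of
#' `max_{j != i} R_ij`. The `classical` variant uses
#' `R_ij = (S_i + S_j) / M_ij`; the `as_printed` variant uses the
#' difference `(S_i - S_j) / M_ij` instead. Smaller values indicate
#' homogeneous, well-separated clusters.
#'
#' @param coords Numeric matrix of embedding coordinates (cells x d).
#' @param labels Integer cluster labels, one per row of `coords`.
#' @param variant `"classical"` (default) or `"as_printed"`.
#' @return The non-negative index.
#' @export
davies_bouldin <- function(coords, labels,
                           variant = c("classical", "as_printed")) {
  variant <- match.arg(variant)
  coords <- as.matrix(coords)
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  K <- length(ids)
  if (K < 2) stop("need at least 2 clusters", call. = FALSE)
  centroids <- t(vapply(ids, function(kk) {
    colMeans(coords[labels == kk, , drop = FALSE])
  }, numeric(ncol(coords))))
  S <- vapply(ids, function(kk) {
    pts <- coords[labels == kk, , drop = FALSE]
    mu <- colMeans(pts)
    sqrt(mean(rowSums(sweep(pts, 2, mu)^2)))
  }, numeric(1))
  Md <- as.matrix(stats::dist(centroids))
  if (any(Md[upper.tri(Md)] == 0)) {
    stop("coincident cluster centroids: M_ij = 0", call. = FALSE)
  }
  D <- vapply(seq_len(K), function(i) {
    r <- vapply(seq_len(K)[-i], function(j) {
      num <- if (variant == "classical") S[i] + S[j] else S[i] - S[j]
      num / Md[i, j]
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(D)
}

#' Adjusted Rand index between two partitions of the same cells
#'
#' Chance-corrected agreement computed from the contingency table with
#' exact binomial-coefficient arithmetic; 1 for identical partitions, about
#' 0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors of equal length, or
#'   [labeled_cells()] tibbles over the same cell set (matched by
#'   `cell_id`).
#' @return The index, in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (is.data.frame(labels_a) && is.data.frame(labels_b)) {
    if (!setequal(labels_a$cell_id, labels_b$cell_id)) {
      stop("label tables cover different cell sets", call. = FALSE)
    }
    labels_b <- labels_b[match(labels_a$cell_id, labels_b$cell_id), ]
    labels_a <- labels_a$label
    labels_b <- labels_b$label
  }
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Mean absolute difference in per-cluster cell counts
#'
#' Mean over the union of cluster ids of the absolute difference between
#' the number of cells carrying that label in the reference and in the
#' synthetic data; clusters absent from one side count zero cells there.
#'
#' @param ref_labels,syn_labels Integer label vectors or [labeled_cells()]
#'   tibbles.
#' @return Non-negative mean absolute count difference.
#' @export
cluster_proportion_mad <- function(ref_labels, syn_labels) {
  if (is.data.frame(ref_labels)) ref_labels <- ref_labels$label
  if (is.data.frame(syn_labels)) syn_labels <- syn_labels$label
  if (!length(ref_labels) || !length(syn_labels)) {
    stop("empty label vector", call. = FALSE)
  }
  ids <- union(unique(ref_labels), unique(syn_labels))
  nr <- vapply(ids, function(kk) sum(ref_labels == kk), numeric(1))
  ns <- vapply(ids, function(kk) sum(syn_labels == kk), numeric(1))
  mean(abs(nr - ns))
}

#' Mean absolute per-gene deviation of a summary statistic
#'
#' Computes one descriptive statistic per gene on the raw counts of the
#' original and synthetic data and returns the mean over genes of the
#' absolute differences. For `cv` (sd/mean), genes with zero mean in
#' either dataset are excluded; their number is attached as attribute
#' `n_excluded`.
#'
#' @param orig,syn [count_matrix()] objects over the identical gene set
#'   and order.
#' @param statistic One of `"median"`, `"iqr"`, `"cv"`, `"zero_fraction"`.
#' @return Non-negative scalar (with `n_excluded` attribute for `cv`).
#' @export
gene_stat_mad <- function(orig, syn,
                          statistic = c("median", "iqr", "cv",
                                        "zero_fraction")) {
  statistic <- match.arg(statistic)
  if (!identical(colnames(orig), colnames(syn))) {
    stop("gene sets/order differ between original and synthetic data",
         call. = FALSE)
  }
  stat_fun <- switch(statistic,
    median = function(v) stats::median(v),
    iqr = function(v) stats::IQR(v),
    cv = function(v) stats::sd(v) / mean(v),
    zero_fraction = function(v) mean(v == 0))
  so <- apply(unclass(orig), 2, stat_fun)
  ss <- apply(unclass(syn), 2, stat_fun)
  if (statistic == "cv") {
    keep <- is.finite(so) & is.finite(ss)
    out <- mean(abs(so[keep] - ss[keep]))
    attr(out, "n_excluded") <- sum(!keep)
    return(out)
  }
  mean(abs(so - ss))
}

#' Check that a generator does not impute artificially omitted values
#'
#' Compares per-gene zero fractions of generated data against the
#' (zero-inflated) corrupted data the generator was trained on. A
#' generated zero fraction well below the corrupted one signals that the
#' model refilled the omitted entries.
#'
#' @param orig Original [count_matrix()] before corruption.
#' @param corrupted The corrupted training matrix (from
#'   [add_artificial_zeros()]).
#' @param generated Synthetic data from a model trained on `corrupted`.
#' @param margin Flag genes whose generated zero fraction falls below the
#'   corrupted one by more than this.
#' @return A list with `mean_abs_gap` (mean over genes of
#'   `|zf_generated - zf_corrupted|`), `flagged` (character vector of
#'   imputation-suspect genes), and the per-gene tibble `per_gene`.
#' @export
zero_preservation_check <- function(orig, corrupted, generated,
                                    margin = 0.1) {
  if (!identical(colnames(orig), colnames(corrupted)) ||
      !identical(colnames(orig), colnames(generated))) {
    stop("gene sets differ between matrices", call. = FALSE)
  }
  zf <- function(m) colMeans(unclass(m) == 0)
  z_orig <- zf(orig); z_corr <- zf(corrupted); z_gen <- zf(generated)
  per_gene <- tibble::tibble(gene_id = colnames(orig),
                             zero_frac_original = z_orig,
                             zero_frac_corrupted = z_corr,
                             zero_frac_generated = z_gen,
                             gap = z_gen - z_corr)
  list(mean_abs_gap = mean(abs(z_gen - z_corr)),
       flagged = colnames(orig)[z_gen < z_corr - margin],
       per_gene = per_gene)
}

#' Evaluate one synthetic dataset against a reference clustering
#'
#' Computes the full report: labels are transferred to the synthetic cells
#' by nearest neighbour in embedding space; the Davies-Bouldin index is
#' computed on the synthetic cells' embedding coordinates under the
#' transferred labels; the adjusted Rand index compares the transferred
#' labels with a de-novo clustering of the synthetic data by the same
#' provider; cluster-proportion and per-gene statistic deviations compare
#' against the original data.
#'
#' @param ref A `"ref_clustering"` of the original data.
#' @param orig The original [count_matrix()].
#' @param syn The synthetic [count_matrix()] (same genes).
#' @param dbi_variant Passed to [davies_bouldin()].
#' @param seed Seed for the de-novo clustering of the synthetic data.
#' @return A one-row tibble: `dbi`, `ari`, `cluster_count_mad`,
#'   `mad_median`, `mad_iqr`, `mad_cv`, `mad_zero_fraction`,
#'   `n_cells_generated`, `n_clusters_syn`.
#' @export
evaluate_synthetic <- function(ref, orig, syn, dbi_variant = "classical",
                               seed = 1L) {
  coords_syn <- ref$project(syn)
  transferred <- transfer_labels(ref, syn, query_coords = coords_syn)
  dbi <- davies_bouldin(coords_syn, transferred$label, variant = dbi_variant)
  denovo <- reference_clustering(syn, seed = seed)
  ari <- adjusted_rand(transferred$label, denovo$labels$label)
  tibble::tibble(
    dbi = dbi,
    ari = ari,
    cluster_count_mad = cluster_proportion_mad(ref$labels, transferred),
    mad_median = gene_stat_mad(orig, syn, "median"),
    mad_iqr = gene_stat_mad(orig, syn, "iqr"),
    mad_cv = as.numeric(gene_stat_mad(orig, syn, "cv")),
    mad_zero_fraction = gene_stat_mad(orig, syn, "zero_fraction"),
    n_cells_generated = nrow(syn),
    n_clusters_syn = denovo$n_clusters
  )
}
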