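#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p-transformed, median-library
#' normalized counts and keeps the top `n_genes`, preserving the original
#' gene order among the selected. A deterministic, lightweight stand-in for
#' heavier model-based HVG selection.
#'
#' @param cm A [count_matrix()].
#' @param n_genes Number of genes to keep (positive, at most `ncol(cm)`).
#' @return A [count_matrix()] with `n_genes` columns.
#' @export
select_hvg <- function(cm, n_genes) {
  if (length(n_genes) != 1 || n_genes <= 0) {
    stop("n_genes must be a positive integer", call. = FALSE)
  }
  if (n_genes > ncol(cm)) {
    stop("n_genes (", n_genes, ") exceeds number of genes (", ncol(cm), ")",
         call. = FALSE)
  }
  v <- hvg_variances(cm)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_genes)])
  count_matrix(unclass(cm)[, keep, drop = FALSE],
               rownames(cm), colnames(cm)[keep])
}

# variance of log1p(counts scaled to the median library size), per gene
hvg_variances <- function(cm) {
  norm <- normalize_log1p(cm)
  apply(norm, 2, stats::var)
}

# log1p of counts rescaled so every cell has the (reference) median library
# size; `target` lets queries be normalized consistently with a reference
normalize_log1p <- function(cm, target = NULL) {
  lib <- rowSums(cm)
  if (is.null(target)) target <- stats::median(lib)
  lib[lib == 0] <- 1
  log1p(unclass(cm) * (target / lib))
}

#' Split cells at random into train and test sets
#'
#' @param cm A [count_matrix()].
#' @param train_frac Fraction of cells in the training split (0 < f < 1);
#'   the training set has `round(train_frac * n)` cells.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with elements `train` and `test`, both [count_matrix()]s
#'   forming a disjoint partition of the input cells.
#' @export
train_test_split <- function(cm, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(cm)
  if (n < 2) stop("need at least 2 cells to split", call. = FALSE)
  n_train <- round(train_frac * n)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(
    train = count_matrix(unclass(cm)[idx, , drop = FALSE],
                         rownames(cm)[idx], colnames(cm)),
    test = count_matrix(unclass(cm)[-idx, , drop = FALSE],
                        rownames(cm)[-idx], colnames(cm))
  )
}

#' Subsample cells into pilot "plates"
#'
#' Draws `n_plates * plate_size` cells uniformly at random without
#' replacement, emulating the capture of pilot data on 384-well plates.
#'
#' @param cm A [count_matrix()].
#' @param n_plates Number of plates.
#' @param plate_size Cells per plate (default 384).
#' @param seed Integer seed.
#' @return A [count_matrix()] of the sampled cells.
#' @export
subsample_plates <- function(cm, n_plates, plate_size = 384L, seed = 1L) {
  n_req <- n_plates * plate_size
  if (n_req > nrow(cm)) {
    stop("requested ", n_req, " cells but only ", nrow(cm), " available",
         call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(cm), n_req))
  count_matrix(unclass(cm)[idx, , drop = FALSE],
               rownames(cm)[idx], colnames(cm))
}
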