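#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-gene parameters of an scDBM fit
#'
#' @param x An `"scdbm"` object.
#' @param ... Unused.
#' @return A tibble with one row per gene: visible bias `a`, inverse
#'   dispersion `theta`, the implied bias-only mean `mu_bias`, and the
#'   per-hidden-unit weights `w1_*`.
#' @export
tidy.scdbm <- function(x, ...) {
  p <- x$params
  W <- p$W1
  colnames(W) <- paste0("w1_", seq_len(ncol(W)))
  dplyr::bind_cols(
    tibble::tibble(gene_id = x$genes, a = p$a, theta = p$theta,
                   mu_bias = p$theta * exp(p$a) / (1 - exp(p$a))),
    tibble::as_tibble(W)
  )
}

#' One-row summary of an scDBM fit
#'
#' @param x An `"scdbm"` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, epochs, and the final
#'   reconstruction moment error.
#' @export
glance.scdbm <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$params$a),
    n_hidden1 = length(x$params$b1),
    n_hidden2 = length(x$params$b2),
    n_cells_trained = x$n_cells_trained,
    epochs = x$config$epochs,
    recon_moment_error = if (nrow(x$history)) {
      utils::tail(x$history$recon_moment_error, 1)
    } else NA_real_
  )
}

#' Tidy per-gene parameters of an NB-VAE fit
#'
#' @param x An `"nbvae"` object.
#' @param ... Unused.
#' @return A tibble with one row per gene: the learned inverse dispersion.
#' @export
tidy.nbvae <- function(x, ...) {
  tibble::tibble(gene_id = x$genes, theta = exp(x$weights$log_theta))
}

#' One-row summary of an NB-VAE fit
#'
#' @param x An `"nbvae"` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, epochs, library-size prior, and
#'   final training ELBO per cell.
#' @export
glance.nbvae <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    latent_dim = x$config$latent_dim,
    hidden_width = x$config$hidden_width,
    n_cells_trained = x$n_cells_trained,
    epochs = x$config$epochs,
    l_mu = x$prior$l_mu,
    l_sd = x$prior$l_sd,
    elbo = if (nrow(x$history)) utils::tail(x$history$elbo, 1) else NA_real_
  )
}

#' Tidy a reference clustering
#'
#' @param x A `"ref_clustering"` object.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `label`, and embedding coordinates
#'   `dim1`, `dim2`.
#' @export
tidy.ref_clustering <- function(x, ...) {
  tibble::tibble(cell_id = x$labels$cell_id, label = x$labels$label,
                 dim1 = x$coords[, 1], dim2 = x$coords[, 2])
}
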