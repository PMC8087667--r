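#' Design of a pilot-study evaluation sweep
#'
#' Describes the full experiment: pilot plates of several sizes are
#' subsampled repeatedly from an original dataset, each generator is
#' trained on the pilot and asked for `target_n` synthetic cells, and the
#' synthetic data are scored against a reference clustering of the
#' original data computed once.
#'
#' @param plate_sizes Pilot sizes in cells (default one to six 384-well
#'   plates).
#' @param n_repeats Subsampling repetitions per size (default 30).
#' @param generators Subset of `"scdbm"`, `"vae-prior"`, `"vae-posterior"`,
#'   `"baseline"`.
#' @param base_seed Base seed; repetition `r` subsamples with seed
#'   `base_seed + r`, and training/generation seeds are derived from a
#'   deterministic counter over (plate size index, repetition).
#' @param target_n Synthetic dataset size; `NULL` means the size of the
#'   original data.
#' @return A list of class `"pilot_design"`.
#' @export
pilot_design <- function(plate_sizes = c(384L, 768L, 1152L, 1536L, 1920L,
                                         2304L),
                         n_repeats = 30L,
                         generators = c("scdbm", "vae-prior",
                                        "vae-posterior", "baseline"),
                         base_seed = 1L, target_n = NULL) {
  generators <- match.arg(generators, several.ok = TRUE)
  stopifnot(all(plate_sizes > 0), n_repeats >= 1)
  structure(list(plate_sizes = as.integer(plate_sizes),
                 n_repeats = as.integer(n_repeats), generators = generators,
                 base_seed = as.integer(base_seed), target_n = target_n),
            class = "pilot_design")
}

#' Train a generator on pilot data and produce synthetic cells
#'
#' Backend dispatcher used by [run_pilot_experiment()] and the CLI.
#'
#' @param backend One of `"scdbm"`, `"vae-prior"`, `"vae-posterior"`,
#'   `"baseline"`.
#' @param pilot Pilot [count_matrix()].
#' @param target_n Number of synthetic cells.
#' @param seed Integer seed (controls training and generation).
#' @param scdbm_cfg,vae_cfg Configurations for the model backends; their
#'   `seed` field is overridden by `seed`.
#' @return A [count_matrix()] of `target_n` synthetic cells.
#' @export
generate_synthetic <- function(backend, pilot, target_n, seed = 1L,
                               scdbm_cfg = scdbm_config(),
                               vae_cfg = nbvae_config()) {
  switch(backend,
    "baseline" = noise_baseline(pilot, target_n, seed = seed),
    "scdbm" = {
      scdbm_cfg$seed <- as.integer(seed)
      fit <- train_scdbm(pilot, scdbm_cfg)
      scdbm_generate(fit, target_n, seed = seed + 1L)
    },
    "vae-prior" = {
      vae_cfg$seed <- as.integer(seed)
      fit <- train_vae(pilot, vae_cfg)
      vae_sample_prior(fit, target_n, seed = seed + 1L)
    },
    "vae-posterior" = {
      vae_cfg$seed <- as.integer(seed)
      fit <- train_vae(pilot, vae_cfg)
      vae_sample_posterior(fit, pilot, target_n, seed = seed + 1L)
    },
    stop("unknown backend: ", backend, call. = FALSE))
}

#' Run the full pilot-study evaluation sweep
#'
#' For every plate size x repetition x generator: subsample a pilot from
#' the original data, train/generate `target_n` synthetic cells, transfer
#' labels from the frozen reference clustering of the original data, and
#' compute the evaluation report. Individual run failures are recorded in
#' the `error` column rather than aborting the sweep. With a `cache_dir`,
#' completed rows are reloaded instead of recomputed.
#'
#' @param original The original [count_matrix()] (ground truth source).
#' @param design A [pilot_design()].
#' @param scdbm_cfg,vae_cfg Backend configurations.
#' @param ref Optional precomputed `"ref_clustering"` of `original`;
#'   computed once here otherwise.
#' @param cache_dir Optional directory for resumable per-run caching.
#' @param dbi_variant Passed to [evaluate_synthetic()].
#' @return A tibble of class `"pilot_results"`, one row per run, with
#'   provenance columns (`generator`, `plate_size`, `repeat_id`, `seed`)
#'   followed by the [evaluate_synthetic()] metrics and `error`.
#' @export
run_pilot_experiment <- function(original, design = pilot_design(),
                                 scdbm_cfg = scdbm_config(),
                                 vae_cfg = nbvae_config(), ref = NULL,
                                 cache_dir = NULL,
                                 dbi_variant = "classical") {
  if (is.null(design$target_n)) design$target_n <- nrow(original)
  max_req <- max(design$plate_sizes)
  if (max_req > nrow(original)) {
    stop("largest plate size (", max_req, ") exceeds original data (",
         nrow(original), " cells)", call. = FALSE)
  }
  if (is.null(ref)) {
    ref <- reference_clustering(original, seed = design$base_seed)
  }
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  rows <- list()
  for (pi in seq_along(design$plate_sizes)) {
    ps <- design$plate_sizes[pi]
    for (r in seq_len(design$n_repeats)) {
      sub_seed <- design$base_seed + r
      run_seed <- design$base_seed + 1000L * pi + r
      pilot <- subsample_plates(original, 1L, plate_size = ps,
                                seed = sub_seed)
      for (gen in design$generators) {
        key <- sprintf("%s_size%d_rep%d", gen, ps, r)
        cache_file <- if (!is.null(cache_dir)) {
          file.path(cache_dir, paste0(key, ".rds"))
        }
        if (!is.null(cache_file) && file.exists(cache_file)) {
          rows[[key]] <- readRDS(cache_file)
          next
        }
        row <- tryCatch({
          syn <- generate_synthetic(gen, pilot, design$target_n,
                                    seed = run_seed,
                                    scdbm_cfg = scdbm_cfg,
                                    vae_cfg = vae_cfg)
          rep <- evaluate_synthetic(ref, original, syn,
                                    dbi_variant = dbi_variant,
                                    seed = run_seed)
          dplyr::bind_cols(
            tibble::tibble(generator = gen, plate_size = ps,
                           repeat_id = r, seed = run_seed),
            rep, tibble::tibble(error = NA_character_))
        }, error = function(e) {
          tibble::tibble(generator = gen, plate_size = ps, repeat_id = r,
                         seed = run_seed, error = conditionMessage(e))
        })
        rows[[key]] <- row
        if (!is.null(cache_file)) saveRDS(row, cache_file)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pilot_results", class(out))
  out
}
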