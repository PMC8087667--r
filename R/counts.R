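#' Construct a validated cell-by-gene count matrix
#'
#' The universal currency of the package: an integer matrix of UMI (or read)
#' counts with cells as rows and genes as columns, identified by unique
#' row and column names.
#'
#' @param counts Numeric matrix of non-negative integers, cells in rows.
#' @param cell_ids,gene_ids Optional character vectors overriding the
#'   dimnames of `counts`. Must be unique and of matching length.
#' @return An integer matrix with class `"count_matrix"` prepended, rownames
#'   set to cell ids and colnames to gene ids.
#' @examples
#' m <- count_matrix(matrix(0:5, 2, 3), c("c1", "c2"), c("g1", "g2", "g3"))
#' dim(m)
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) {
    cell_ids <- sprintf("cell%d", seq_len(nrow(counts)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gene%d", seq_len(ncol(counts)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts)) {
    stop("length(cell_ids) [", length(cell_ids), "] != number of rows [",
         nrow(counts), "]", call. = FALSE)
  }
  if (length(gene_ids) != ncol(counts)) {
    stop("length(gene_ids) [", length(gene_ids), "] != number of columns [",
         ncol(counts), "]", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  validate_counts(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_ids, gene_ids)
  class(counts) <- c("count_matrix", class(matrix()))
  counts
}

#' Validate that a matrix contains non-negative integer counts
#'
#' @param counts A numeric matrix.
#' @return Invisibly `TRUE`; otherwise an error naming the first offending
#'   entry by its (row, column) coordinate.
#' @export
validate_counts <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(counts))
    stop("invalid count at (row ", ij[1], ", col ", ij[2], "): ",
         counts[bad[1]], " (counts must be non-negative integers)",
         call. = FALSE)
  }
  invisible(TRUE)
}

cell_ids <- function(cm) rownames(cm)
gene_ids <- function(cm) colnames(cm)

#' Read a count matrix from disk
#'
#' Supports MatrixMarket coordinate-integer files with `barcodes.tsv` /
#' `genes.tsv` sidecars (10x-style, genes as rows on disk by default) and
#' dense CSV/TSV with a header row of gene ids and a first column of cell
#' ids. Always returns cells x genes regardless of on-disk orientation.
#'
#' @param path Path to the `.mtx` file or the CSV/TSV file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`; `"auto"` guesses from the
#'   file extension.
#' @param cells_as_rows For MTX only: set `TRUE` when the on-disk matrix
#'   already stores cells as rows (the default follows the dominant
#'   genes-as-rows convention and transposes on load).
#' @return A [count_matrix()].
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        cells_as_rows = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot guess format from '", path, "'",
                          call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    bc <- file.path(dir, "barcodes.tsv")
    gn <- file.path(dir, "genes.tsv")
    if (!file.exists(bc) || !file.exists(gn)) {
      stop("MTX sidecars barcodes.tsv / genes.tsv missing next to ", path,
           call. = FALSE)
    }
    barcodes <- readLines(bc)
    genes <- readLines(gn)
    if (!cells_as_rows) m <- t(m)
    if (nrow(m) != length(barcodes) || ncol(m) != length(genes)) {
      stop("sidecar length mismatch: matrix is ", nrow(m), " cells x ",
           ncol(m), " genes but barcodes.tsv has ", length(barcodes),
           " and genes.tsv has ", length(genes), " entries", call. = FALSE)
    }
    return(count_matrix(m, barcodes, genes))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(as.matrix(df), rownames(df), colnames(df))
}

#' Write a count matrix to disk
#'
#' Round-trips losslessly through [read_counts()]: integer values are
#' preserved exactly in both formats.
#'
#' @param cm A [count_matrix()].
#' @param path Output path (`.mtx` files get `barcodes.tsv`/`genes.tsv`
#'   sidecars written alongside).
#' @inheritParams read_counts
#' @return Invisibly, `path`.
#' @export
write_counts <- function(cm, path, format = c("auto", "mtx", "csv", "tsv"),
                         cells_as_rows = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot guess format from '", path, "'",
                          call. = FALSE))
  }
  if (format == "mtx") {
    m <- Matrix::Matrix(unclass(cm), sparse = TRUE)
    if (!cells_as_rows) m <- Matrix::t(m)
    status <- try(Matrix::writeMM(m, path), silent = TRUE)
    if (inherits(status, "try-error")) {
      stop("failed to write MTX to ", path, ": ",
           attr(status, "condition")$message, call. = FALSE)
    }
    dir <- dirname(path)
    writeLines(rownames(cm), file.path(dir, "barcodes.tsv"))
    writeLines(colnames(cm), file.path(dir, "genes.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(cell_id = rownames(cm), unclass(cm), check.names = FALSE)
  colnames(df) <- c("cell_id", colnames(cm))
  status <- try(utils::write.table(df, path, sep = sep, quote = FALSE,
                                   row.names = FALSE), silent = TRUE)
  if (inherits(status, "try-error")) {
    stop("failed to write counts to ", path, ": ",
         attr(status, "condition")$message, call. = FALSE)
  }
  invisible(path)
}

#' Read / write cluster labels as two-column TSV
#'
#' Labels are carried as a tibble with columns `cell_id` (character) and
#' `label` (0-based contiguous integers).
#'
#' @param path Path to a two-column TSV (`cell_id`, `label`).
#' @return A tibble with columns `cell_id`, `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  labeled_cells(df$cell_id, df$label)
}

#' @rdname read_labels
#' @param labels A tibble as returned by [labeled_cells()].
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a validated label table
#'
#' @param cell_ids Character vector, one entry per cell, duplicate-free.
#' @param labels Non-negative integer cluster ids. With
#'   `contiguous = TRUE` (the default for freshly created partitions) the
#'   labels must cover `0..K-1` with no gaps; label tables for subsets of
#'   cells (e.g. transferred labels) may skip ids.
#' @param contiguous Enforce gap-free 0-based labels.
#' @return A tibble with columns `cell_id` and `label`.
#' @export
labeled_cells <- function(cell_ids, labels, contiguous = FALSE) {
  cell_ids <- as.character(cell_ids)
  labels <- as.integer(labels)
  if (length(cell_ids) != length(labels)) {
    stop("cell_ids and labels differ in length", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  if (length(labels) && min(labels) < 0) {
    stop("labels must be non-negative", call. = FALSE)
  }
  if (contiguous) {
    u <- sort(unique(labels))
    if (length(u) && !identical(u, seq(0L, max(labels)))) {
      stop("labels must be 0-based and contiguous; saw {",
           paste(u, collapse = ", "), "}", call. = FALSE)
    }
  }
  tibble::tibble(cell_id = cell_ids, label = labels)
}
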