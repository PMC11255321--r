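#' Read an expression matrix
#'
#' Supports Matrix Market triplet directories in the 10x dialect
#' (`matrix.mtx` plus `genes.tsv`/`features.tsv` and `barcodes.tsv`
#' sidecars) and dense CSV/TSV with gene rows, a header of cell ids, and
#' gene ids in the first column. The internal orientation is genes x
#' cells; a cells x genes table is transposed with a warning when the
#' sidecar dimensions disambiguate it. Negative entries are rejected.
#'
#' @param path File (csv/tsv/mtx) or 10x-style directory.
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"`, or `"tsv"`.
#'   `.h5ad` containers are not supported by this build and raise an
#'   informative error.
#' @return genes x cells numeric matrix with dimnames (sparse input is
#'   returned as a `dgCMatrix`).
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx"
    else if (grepl("\\.h5ad$", path)) stop(
      "h5ad containers are not supported; export to Matrix Market or CSV")
    else if (grepl("\\.tsv$|\\.txt$", path)) "tsv"
    else "csv"
  }
  if (format == "mtx") {
    read_expression_mtx(path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                             check.names = FALSE)
    X <- as.matrix(tab)
    if (!is.numeric(X)) stop("malformed table: non-numeric entries in ", path)
    if (any(X < 0)) stop("negative expression entries in ", path)
    X
  }
}

read_expression_mtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes <- Filter(file.exists,
                    file.path(path, c("genes.tsv", "features.tsv")))[1]
    barcodes <- file.path(path, "barcodes.tsv")
  } else {
    mtx <- path
    base <- dirname(path)
    genes <- Filter(file.exists,
                    file.path(base, c("genes.tsv", "features.tsv")))[1]
    barcodes <- file.path(base, "barcodes.tsv")
  }
  if (!file.exists(mtx)) stop("matrix.mtx not found under ", path)
  X <- Matrix::readMM(mtx)
  if (any(X@x < 0)) stop("negative expression entries in ", mtx)
  gene_ids <- if (!is.na(genes) && file.exists(genes))
    utils::read.delim(genes, header = FALSE)[[1]] else NULL
  cell_ids <- if (file.exists(barcodes))
    utils::read.delim(barcodes, header = FALSE)[[1]] else NULL
  if (!is.null(gene_ids) && !is.null(cell_ids)) {
    if (nrow(X) == length(cell_ids) && ncol(X) == length(gene_ids) &&
        length(gene_ids) != length(cell_ids)) {
      warning("matrix stored cells x genes; transposing to genes x cells")
      X <- Matrix::t(X)
    }
    if (nrow(X) != length(gene_ids) || ncol(X) != length(cell_ids))
      stop(sprintf("sidecar mismatch: matrix %d x %d vs %d genes, %d barcodes",
                   nrow(X), ncol(X), length(gene_ids), length(cell_ids)))
    dimnames(X) <- list(as.character(gene_ids), as.character(cell_ids))
  }
  X
}

#' Write an expression matrix
#'
#' @param X genes x cells matrix.
#' @param path Output file (`.csv`/`.tsv`) or directory for Matrix Market
#'   triplets.
#' @param format `"csv"`, `"tsv"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(X), sparse = TRUE),
                                            "CsparseMatrix"), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(X), file.path(path, "genes.tsv"))
    writeLines(colnames(X), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene = rownames(X), as.matrix(X), check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write an affinity graph as an edge list
#'
#' Upper-triangle edges (i, j, weight) above a threshold, as TSV.
#'
#' @param A `q_affinity` object or symmetric matrix.
#' @param path Output TSV path.
#' @param threshold Minimum weight to keep; default 0 (all edges).
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(A, path, threshold = 0) {
  if (inherits(A, "q_affinity")) A <- A$A
  ut <- upper.tri(A)
  keep <- ut & A > threshold
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(A)
  df <- data.frame(
    i = if (is.null(ids)) idx[, 1] else ids[idx[, 1]],
    j = if (is.null(ids)) idx[, 2] else ids[idx[, 2]],
    weight = A[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cluster labels
#'
#' Two-column CSV (cell_id, cluster).
#'
#' @param labels Named or unnamed label vector.
#' @param path Output CSV path.
#' @param ids Cell identifiers (defaults to names of `labels`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, ids = names(labels)) {
  if (is.null(ids)) ids <- paste0("cell", seq_along(labels))
  utils::write.table(data.frame(cell_id = ids, cluster = unname(labels)),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of every parameter of a run (including `q`, `phi`, `k`, and
#' the seed) so the run can be reproduced exactly.
#'
#' @param mode Pipeline mode string.
#' @param params [qparams()] used.
#' @param seed Integer seed.
#' @param path Output JSON path.
#' @param extra Named list of additional parameters to record.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(mode, params, seed, path, extra = list()) {
  manifest <- c(list(mode = mode, q = params$q, alpha = params$alpha,
                     phi = params$phi, k = params$k,
                     quantile = params$quantile, seed = seed),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(manifest)
}
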