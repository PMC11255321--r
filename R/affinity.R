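#' Library-size normalization and log transform
#'
#' Standard preprocessing for raw counts: scale each cell (column) to the
#' median total count across cells, then apply `log1p`. Pass-through for
#' data that is already normalized.
#'
#' @param X genes x cells non-negative matrix.
#' @return Matrix of the same shape.
#' @export
normalize_cells <- function(X) {
  X <- check_expression(X)
  totals <- colSums(X)
  if (any(totals == 0)) stop("cells with zero total counts cannot be normalized")
  log1p(sweep(X, 2, median(totals) / totals, `*`))
}

check_expression <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric genes x cells matrix")
  if (any(!is.finite(X))) stop("`X` must be finite")
  if (any(X < 0)) stop("`X` must be non-negative")
  if (nrow(X) < 1L || ncol(X) < 2L) stop("`X` needs at least 1 gene and 2 cells")
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("cell", seq_len(ncol(X)))
  X
}

#' Inner bandwidth from per-gene scatters
#'
#' For each gene, the scatter is the average squared difference over all
#' unordered pairs of distinct cells, equal to twice the sample variance
#' (computed in O(mn), no pair enumeration). The inner bandwidth is the
#' square root of a quantile of these scatters; the median by default, so
#' that a typical gene's pairwise difference lands at the soft threshold.
#'
#' @param X genes x cells matrix.
#' @param quantile Fraction in (0, 1); default 0.5.
#' @return Positive scalar `phi`.
#' @examples
#' X <- rbind(g1 = c(0, 2), g2 = c(1, 1), g3 = c(0, 4))
#' colnames(X) <- c("a", "b")
#' inner_bandwidth(X)  # scatters 4, 0, 16 -> median 4 -> phi 2
#' @export
inner_bandwidth <- function(X, quantile = 0.5) {
  X <- check_expression(X)
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must be in (0, 1)")
  scatters <- 2 * apply(X, 1, var)
  phi2 <- stats::quantile(scatters, quantile, names = FALSE)
  if (phi2 <= 0)
    stop("inner bandwidth would be zero: the chosen quantile of gene scatters ",
         "vanishes (too many constant genes)")
  sqrt(phi2)
}

#' Pairwise squared q-norms between cells
#'
#' Entry (i, j) is the squared q-diffused norm of `(x_i - x_j) / phi`.
#' Linear time in the number of genes per pair via the log-domain identity.
#'
#' @param X genes x cells matrix.
#' @param params [qparams()] with `phi` set, or `NA` to apply the
#'   inner-bandwidth heuristic.
#' @return Symmetric n x n matrix with zero diagonal. The `phi` actually
#'   used is attached as attribute `"phi"`.
#' @export
pairwise_qnorms <- function(X, params = qparams()) {
  X <- check_expression(X)
  stopifnot(inherits(params, "qparams"))
  phi <- if (is.na(params$phi)) inner_bandwidth(X, params$quantile) else params$phi
  D <- cpp_qnorm_pairwise(X / phi, params$alpha)
  dimnames(D) <- list(colnames(X), colnames(X))
  attr(D, "phi") <- phi
  D
}

#' Adaptive outer bandwidths
#'
#' Per-cell kernel scale: the k-th nearest q-diffused norm (square root of
#' the k-th smallest off-diagonal entry of that cell's row of squared
#' norms). Cells duplicated in the data would get a zero bandwidth; those
#' are repaired to the smallest positive value in the row, with a warning.
#'
#' @param D Symmetric matrix of squared deformed norms.
#' @param k Neighbourhood size, 1 <= k <= n - 1.
#' @return Positive numeric vector of length n.
#' @export
adaptive_outer_bandwidths <- function(D, k) {
  rho <- adaptive_rho(D, k, on_all_zero = "error")
  if (is.null(names(rho)) && !is.null(rownames(D))) names(rho) <- rownames(D)
  rho
}

adaptive_rho <- function(D, k, on_all_zero = c("error", "one")) {
  on_all_zero <- match.arg(on_all_zero)
  n <- nrow(D)
  if (k < 1 || k > n - 1) stop("`k` must satisfy 1 <= k <= n - 1")
  rho2 <- vapply(seq_len(n), function(i) {
    sort(D[i, -i], partial = k)[k]
  }, numeric(1))
  zero <- which(rho2 <= 0)
  if (length(zero)) {
    repl <- vapply(zero, function(i) {
      pos <- D[i, -i]
      pos <- pos[pos > 0]
      if (length(pos)) min(pos) else NA_real_
    }, numeric(1))
    if (anyNA(repl)) {
      if (on_all_zero == "error")
        stop("cell(s) ", paste(head(zero[is.na(repl)], 5), collapse = ", "),
             " are duplicates of every other cell; outer bandwidth undefined")
      repl[is.na(repl)] <- 1
    }
    warning(length(zero), " cell(s) had zero k-th neighbour distance ",
            "(duplicated cells); bandwidth repaired to the nearest positive value")
    rho2[zero] <- repl
  }
  sqrt(rho2)
}

#' Symmetrized affinity matrix
#'
#' Applies the deformed kernel with per-origin adaptive bandwidths,
#' `A~[i, j] = exp_q(-D[i, j] / rho_i^2)` (anisotropic: the scale belongs
#' to the origin cell), then symmetrifies arithmetically
#' `A = (A~ + t(A~)) / 2`. The Gaussian variant replaces `exp_q` by `exp`
#' and is the q -> 1 limit used as the undeformed baseline.
#'
#' @param D Pairwise squared-norm matrix (from [pairwise_qnorms()] or
#'   squared Euclidean distances for the Gaussian baseline).
#' @param rho Per-cell outer bandwidths.
#' @param params [qparams()]; only `q` is used here.
#' @param kernel `"q"` (deformed) or `"gaussian"`.
#' @return An object of class `q_affinity`: list with the symmetric matrix
#'   `A` (entries in (0, 1], unit diagonal), `rho`, `params`, `kernel`, and
#'   the `phi` carried on `D` if present.
#' @export
affinity_matrix <- function(D, rho, params = qparams(), kernel = c("q", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(params, "qparams"))
  if (length(rho) != nrow(D)) stop("`rho` length must match `D`")
  if (any(rho <= 0)) stop("`rho` must be positive")
  E <- -sweep(D, 1, rho^2, `/`)
  At <- if (kernel == "q") exp_q(E, params$q) else exp(E)
  A <- (At + t(At)) / 2
  attr(A, "phi") <- NULL
  diag(A) <- 1
  structure(
    list(A = A, rho = rho, params = params, kernel = kernel,
         phi = attr(D, "phi")),
    class = "q_affinity"
  )
}

#' @method print q_affinity
#' @export
print.q_affinity <- function(x, ...) {
  cat(sprintf("q_affinity: %d cells, %s kernel, q = %g, k = %d, phi = %s\n",
              nrow(x$A), x$kernel, x$params$q, x$params$k,
              if (is.null(x$phi)) "?" else format(x$phi, digits = 4)))
  cat(sprintf("  rho: [%.4g, %.4g]\n", min(x$rho), max(x$rho)))
  invisible(x)
}

#' One-call affinity graph from an expression matrix
#'
#' Convenience pipeline: optional count normalization, inner bandwidth by
#' the scatter-quantile heuristic, pairwise deformed (or Euclidean) norms,
#' adaptive outer bandwidths, symmetrized affinities.
#'
#' Dense n x n storage is used; inputs beyond 20,000 cells are refused
#' (compute block-wise and assemble a sparse graph instead).
#'
#' @inheritParams pairwise_qnorms
#' @param kernel `"q"` or `"gaussian"` (undeformed baseline with the same
#'   adaptive-bandwidth construction and the same `phi` scaling).
#' @param normalize If `TRUE`, apply [normalize_cells()] first (for raw
#'   counts); default `FALSE` for pre-normalized input.
#' @return A `q_affinity` object.
#' @examples
#' X <- matrix(rexp(50 * 20), 50, 20)
#' g <- q_affinity(X, qparams(k = 5))
#' range(g$A)
#' @export
q_affinity <- function(X, params = qparams(), kernel = c("q", "gaussian"),
                       normalize = FALSE) {
  kernel <- match.arg(kernel)
  X <- check_expression(X)
  if (ncol(X) > 20000L)
    stop("dense affinity storage is capped at 20,000 cells; ",
         "compute block-wise for larger data")
  if (normalize) X <- normalize_cells(X)
  phi <- if (is.na(params$phi)) inner_bandwidth(X, params$quantile) else params$phi
  if (kernel == "q") {
    D <- cpp_qnorm_pairwise(X / phi, params$alpha)
  } else {
    D <- euclidean_sq_pairwise(X / phi)
  }
  dimnames(D) <- list(colnames(X), colnames(X))
  attr(D, "phi") <- phi
  rho <- adaptive_rho(D, params$k, on_all_zero = "error")
  affinity_matrix(D, rho, params, kernel = kernel)
}

# squared Euclidean distances between columns, clamped at 0
euclidean_sq_pairwise <- function(X) {
  ss <- colSums(X^2)
  D <- outer(ss, ss, `+`) - 2 * crossprod(X)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Leiden community detection on an affinity graph
#'
#' The symmetric affinity matrix, diagonal removed, is taken as a weighted
#' undirected adjacency matrix and partitioned by the Leiden algorithm
#' optimizing modularity. Deterministic for a given seed.
#'
#' @param A A `q_affinity` object or a symmetric affinity matrix.
#' @param resolution Modularity resolution, > 0; default 1.
#' @param seed Integer seed.
#' @return Integer cluster labels (1-based), named by cell id.
#' @export
leiden_cluster <- function(A, resolution = 1, seed = 1) {
  if (inherits(A, "q_affinity")) A <- A$A
  if (!is.matrix(A) || nrow(A) != ncol(A) || nrow(A) < 1L)
    stop("`A` must be a non-empty square affinity matrix")
  if (resolution <= 0) stop("`resolution` must be positive")
  W <- A
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  labels <- as.integer(igraph::membership(cl))
  names(labels) <- rownames(A)
  labels
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to relabelling), expectation 0 under
#' independent random labelling.
#'
#' @param labels,truth Vectors of cluster assignments, equal length.
#' @return A scalar <= 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand_index <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("partitions must have equal length")
  tab <- table(labels, truth)
  n <- length(labels)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}
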