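#' Bundle expression and spatial coordinates
#'
#' @param expr genes x cells non-negative matrix.
#' @param coords n x 2 matrix of spatial positions (rows follow the cells
#'   of `expr`).
#' @return Object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(expr, coords) {
  expr <- check_expression(expr)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L || any(!is.finite(coords)))
    stop("`coords` must be a finite n x 2 numeric matrix")
  if (nrow(coords) != ncol(expr))
    stop("`coords` rows must match the number of cells in `expr`")
  rownames(coords) <- colnames(expr)
  structure(list(expr = expr, coords = coords), class = "spatial_dataset")
}

#' @method print spatial_dataset
#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d genes x %d cells with 2-D coordinates\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' Parcel a tissue into rexels
#'
#' Approximate Voronoi parcellation of the spatial coordinates by repeated
#' k-means ("rexels": region-level pixels). The best of `nstart` seeded
#' initializations (lowest within-cluster sum of squares) is kept; every
#' rexel is non-empty by construction.
#'
#' @param coords n x 2 spatial positions.
#' @param R Number of rexels, 2 <= R <= n. Typical use takes multiples
#'   of 32.
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts; default 10.
#' @return Object of class `rexel_map`: list with `assignment` (length n,
#'   values 1..R), `centroids` (R x 2), `R`.
#' @export
rexelate <- function(coords, R, seed = 1, nstart = 10) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (R > n) stop("`R` must not exceed the number of cells")
  if (R < 2) stop("`R` must be at least 2")
  set.seed(seed)
  km <- kmeans(coords, centers = R, nstart = nstart, iter.max = 100)
  structure(list(assignment = km$cluster, centroids = km$centers, R = R),
            class = "rexel_map")
}

#' Squared maximum mean discrepancy between two cell samples
#'
#' Biased (V-statistic) squared MMD with the deformed or Gaussian kernel:
#' mean kernel within sample a, plus mean within sample b, minus twice the
#' mean between. Zero for identical multisets; small negative values from
#' the non-PSD adaptive kernel are clamped at 0.
#'
#' By default the kernel is adaptive: the outer bandwidth of each origin
#' point is its k-th nearest deformed norm within the pooled two-sample
#' comparison set (so each pairwise rexel comparison carries its own
#' scales), and the kernel matrix is symmetrized arithmetically. Pass a
#' fixed `rho` to override.
#'
#' @param Xa,Xb genes x cells matrices (same gene dimension), both
#'   non-empty.
#' @param kernel `"q"` or `"gaussian"`.
#' @param params [qparams()]; `phi` must be set (compute it once per
#'   dataset with [inner_bandwidth()]); `k` defaults to 16 via
#'   [rexel_distances()] for segmentation use.
#' @param rho Optional fixed outer bandwidth (scalar); `NULL` (default)
#'   for the adaptive per-point bandwidth.
#' @param unbiased If `TRUE`, exclude self-pairs from the within-sample
#'   means (unbiased U-statistic variant). Default `FALSE`.
#' @return Non-negative scalar.
#' @export
mmd_sq <- function(Xa, Xb, kernel = c("q", "gaussian"), params = qparams(k = 16),
                   rho = NULL, unbiased = FALSE) {
  kernel <- match.arg(kernel)
  if (is.vector(Xa)) Xa <- matrix(Xa, nrow = 1)
  if (is.vector(Xb)) Xb <- matrix(Xb, nrow = 1)
  na <- ncol(Xa); nb <- ncol(Xb)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty")
  if (nrow(Xa) != nrow(Xb)) stop("gene dimensions differ")
  phi <- if (is.na(params$phi)) 1 else params$phi
  Z <- cbind(Xa, Xb) / phi
  n <- na + nb
  D <- if (kernel == "q") cpp_qnorm_pairwise(Z, params$alpha) else
    euclidean_sq_pairwise(Z)
  if (is.null(rho)) {
    k_eff <- min(params$k, n - 1L)
    rho_vec <- suppressWarnings(adaptive_rho(D, k_eff, on_all_zero = "one"))
  } else {
    if (rho <= 0) stop("`rho` must be positive")
    rho_vec <- rep(rho, n)
  }
  E <- -sweep(D, 1, rho_vec^2, `/`)
  Kt <- if (kernel == "q") exp_q(E, params$q) else exp(E)
  K <- (Kt + t(Kt)) / 2
  ia <- seq_len(na); ib <- na + seq_len(nb)
  if (unbiased) {
    waa <- if (na > 1) (sum(K[ia, ia]) - na) / (na * (na - 1)) else 0
    wbb <- if (nb > 1) (sum(K[ib, ib]) - nb) / (nb * (nb - 1)) else 0
  } else {
    waa <- mean(K[ia, ia]); wbb <- mean(K[ib, ib])
  }
  max(0, waa + wbb - 2 * mean(K[ia, ib, drop = FALSE]))
}

#' Pairwise MMD distances between rexels
#'
#' Distance matrix over rexels: `D[i, j] = sqrt(max(mmd_sq_ij, 0))` where
#' each rexel pair is compared as two samples of cell transcriptomes. The
#' inner bandwidth is computed once from the full dataset (scatter-quantile
#' heuristic) unless `params$phi` is set; the outer bandwidth is adaptive
#' within each pooled pair with `k = 16` by default, reflecting the small
#' per-comparison sample sizes.
#'
#' @param data A [spatial_dataset()].
#' @param rmap A [rexelate()] map.
#' @param params [qparams()] with `k = 16` default.
#' @param kernel `"q"` or `"gaussian"`.
#' @return R x R symmetric matrix, zero diagonal, with attribute
#'   `metric_tag` (`"mmd-q"` or `"mmd-gaussian"`).
#' @export
rexel_distances <- function(data, rmap, params = qparams(k = 16),
                            kernel = c("q", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(data, "spatial_dataset"), inherits(rmap, "rexel_map"))
  if (is.na(params$phi)) {
    params$phi <- inner_bandwidth(data$expr, params$quantile)
  }
  R <- rmap$R
  cells <- split(seq_len(ncol(data$expr)), rmap$assignment)
  if (length(cells) != R) stop("rexel map has empty rexels")
  D <- matrix(0, R, R)
  for (i in seq_len(R - 1)) {
    Xi <- data$expr[, cells[[i]], drop = FALSE]
    for (j in seq((i + 1), R)) {
      m2 <- mmd_sq(Xi, data$expr[, cells[[j]], drop = FALSE],
                   kernel = kernel, params = params)
      D[i, j] <- D[j, i] <- sqrt(max(m2, 0))
    }
  }
  attr(D, "metric_tag") <- paste0("mmd-", kernel)
  D
}

#' Baseline rexel distances: PCA of mean expression
#'
#' Comparator for the distributional distances: each rexel is reduced to
#' its average expression vector, rexels are projected onto principal
#' components, and Euclidean distances are taken in PC space.
#'
#' @inheritParams rexel_distances
#' @param n_pcs Number of principal components (capped by data rank).
#' @return R x R symmetric matrix, zero diagonal, `metric_tag`
#'   `"mean-pca"`.
#' @export
rexel_pca_distances <- function(data, rmap, n_pcs = 10) {
  stopifnot(inherits(data, "spatial_dataset"), inherits(rmap, "rexel_map"))
  cells <- split(seq_len(ncol(data$expr)), rmap$assignment)
  means <- t(vapply(cells, function(ix)
    rowMeans(data$expr[, ix, drop = FALSE]), numeric(nrow(data$expr))))
  n_pcs <- min(n_pcs, nrow(means) - 1L, ncol(means))
  pcs <- prcomp(means, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  D <- as.matrix(dist(pcs))
  dimnames(D) <- NULL
  attr(D, "metric_tag") <- "mean-pca"
  D
}

#' Segment rexels from a distance matrix
#'
#' Community path: distances are converted to affinities by
#' `exp(-D^2 / sigma^2)` with `sigma` the median off-diagonal distance,
#' then Leiden community detection (modularity) is run on the
#' zero-diagonal graph. Hierarchical path: Ward linkage on the distances,
#' cut to `n_clusters`.
#'
#' @param D R x R symmetric distance matrix.
#' @param method `"community"` or `"hierarchical"`.
#' @param resolution Leiden resolution (community path), default 1.
#' @param n_clusters Number of clusters (hierarchical path).
#' @param seed Integer seed (community path).
#' @return Integer labels of length R.
#' @export
segment_rexels <- function(D, method = c("community", "hierarchical"),
                           resolution = 1, n_clusters = NULL, seed = 1) {
  method <- match.arg(method)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("`D` must be square")
  off <- D[row(D) != col(D)]
  if (all(off == 0)) {
    warning("degenerate all-zero distance matrix; returning a single segment")
    return(rep(1L, nrow(D)))
  }
  if (method == "community") {
    sigma <- median(off[off > 0])
    A <- exp(-D^2 / sigma^2)
    leiden_cluster(A, resolution = resolution, seed = seed)
  } else {
    if (is.null(n_clusters)) stop("hierarchical segmentation needs `n_clusters`")
    hc <- hclust(as.dist(D), method = "ward.D2")
    unname(cutree(hc, k = n_clusters))
  }
}

#' Spatial contiguity of a rexel clustering
#'
#' Mean silhouette of the transcriptomic cluster labels computed on
#' Euclidean distances between rexel centroids: high values mean the
#' clusters are spatially contiguous. Singleton clusters contribute a
#' silhouette of 0.
#'
#' @param labels Cluster labels, length R, at least two distinct values.
#' @param centroids R x 2 rexel centers.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
spatial_silhouette <- function(labels, centroids) {
  centroids <- as.matrix(centroids)
  if (length(labels) != nrow(centroids))
    stop("`labels` length must match `centroids` rows")
  if (length(unique(labels)) < 2L)
    stop("silhouette is undefined for a single cluster")
  sil <- cluster::silhouette(as.integer(as.factor(labels)), dist(centroids))
  mean(sil[, "sil_width"])
}
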