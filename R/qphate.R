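#' Diffusion-potential embedding with the deformed kernel
#'
#' A PHATE-style embedding driven by the q-diffused affinity matrix:
#' (1) build the symmetrized adaptive-bandwidth affinity `A`;
#' (2) row-normalize it (self-affinity retained) into a Markov transition
#' matrix `P`; (3) diffuse `P^t`, with `t` chosen automatically at the knee
#' of the von Neumann entropy of the diffusion operator when `t = "auto"`;
#' (4) form potential distances between rows of `-log(P^t)` with a floor
#' `eps` on probabilities; (5) embed by metric MDS (SMACOF, classical-MDS
#' initialization).
#'
#' @inheritParams q_affinity
#' @param t Diffusion time: positive integer or `"auto"` (von Neumann
#'   entropy knee, capped at `t_max`).
#' @param d Output dimensionality, default 2.
#' @param seed Integer seed (the pipeline is deterministic; the seed fixes
#'   RNG state for reproducibility of the full run contract).
#' @param t_max Cap for automatic `t`; default 100.
#' @param eps Probability floor in the potential transform; default 1e-7.
#' @return Object of class `qphate_embedding`: list with `coords` (n x d,
#'   rows in input cell order), `t`, `params`, `kernel`.
#' @examples
#' X <- matrix(rexp(30 * 40), 30, 40)
#' emb <- qphate(X, qparams(k = 8), t = 5)
#' dim(emb$coords)
#' @export
qphate <- function(X, params = qparams(), kernel = c("q", "gaussian"),
                   t = "auto", d = 2, seed = 1, t_max = 100, eps = 1e-7,
                   normalize = FALSE) {
  kernel <- match.arg(kernel)
  X <- check_expression(X)
  if (ncol(X) < d + 1) stop("need at least d + 1 cells")
  set.seed(seed)
  graph <- q_affinity(X, params, kernel = kernel, normalize = normalize)
  A <- graph$A
  P <- A / rowSums(A)

  if (identical(t, "auto")) {
    t <- vne_knee(P, t_max)
  } else if (!is.numeric(t) || t < 1 || t != round(t)) {
    stop("`t` must be a positive integer or \"auto\"")
  }

  Pt <- matpow(P, as.integer(t))
  if (any(A <= 1e-300) && is_disconnected(A))
    warning("affinity graph is disconnected; components embedded jointly ",
            "with the probability floor preventing infinite potentials")
  U <- -log(pmax(Pt, eps))
  pot <- dist(U)
  coords <- smacof_mds(as.matrix(pot), d)
  rownames(coords) <- colnames(X)
  colnames(coords) <- paste0("dim", seq_len(d))
  structure(list(coords = coords, t = as.integer(t), params = graph$params,
                 kernel = kernel, phi = graph$phi),
            class = "qphate_embedding")
}

#' @method print qphate_embedding
#' @export
print.qphate_embedding <- function(x, ...) {
  cat(sprintf("qphate_embedding: %d cells -> %d dims, t = %d, %s kernel\n",
              nrow(x$coords), ncol(x$coords), x$t, x$kernel))
  invisible(x)
}

is_disconnected <- function(A, tol = 1e-12) {
  W <- A
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W > tol, mode = "undirected")
  igraph::count_components(g) > 1
}

# von Neumann entropy knee: entropy of the diffusion-operator spectrum at
# each power t; knee = point of maximum distance from the chord between the
# entropy curve's endpoints.
vne_knee <- function(P, t_max) {
  ev <- abs(Re(eigen(P, only.values = TRUE)$values))
  ts <- seq_len(t_max)
  H <- vapply(ts, function(t) {
    p <- ev^t
    s <- sum(p)
    if (s <= 0) return(0)
    p <- p / s
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  x1 <- ts[1]; y1 <- H[1]; x2 <- ts[t_max]; y2 <- H[t_max]
  num <- abs((y2 - y1) * ts - (x2 - x1) * H + x2 * y1 - y2 * x1)
  max(2L, ts[which.max(num)])
}

matpow <- function(P, t) {
  out <- NULL
  base <- P
  while (t > 0) {
    if (t %% 2 == 1) out <- if (is.null(out)) base else out %*% base
    base <- base %*% base
    t <- t %/% 2
  }
  out
}

# Metric MDS by SMACOF majorization from a classical-MDS start.
smacof_mds <- function(Delta, d, iters = 100, tol = 1e-9) {
  n <- nrow(Delta)
  Z <- cmdscale(Delta, k = d)
  if (ncol(Z) < d) Z <- cbind(Z, matrix(0, n, d - ncol(Z)))
  dz <- function(Z) as.matrix(dist(Z))
  stress <- function(DZ) sum((Delta - DZ)^2) / 2
  DZ <- dz(Z)
  s_old <- stress(DZ)
  for (i in seq_len(iters)) {
    B <- ifelse(DZ > 0, -Delta / DZ, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Z <- (B %*% Z) / n
    DZ <- dz(Z)
    s_new <- stress(DZ)
    if (s_old - s_new <= tol * max(s_old, 1e-300)) break
    s_old <- s_new
  }
  Z
}

#' @rdname qphate
#' @param object A `qphate_embedding`.
#' @param colour Optional vector to colour cells by (e.g. cluster labels).
#' @param ... Unused.
#' @export
autoplot.qphate_embedding <- function(object, colour = NULL, ...) {
  df <- tibble::tibble(dim1 = object$coords[, 1], dim2 = object$coords[, 2])
  if (!is.null(colour)) {
    df$group <- as.factor(colour)
    ggplot2::ggplot(df, ggplot2::aes(dim1, dim2, colour = group)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(colour = NULL, x = "qPHATE 1", y = "qPHATE 2")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(dim1, dim2)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "qPHATE 1", y = "qPHATE 2")
  }
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
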