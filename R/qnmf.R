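#' Graph-regularized nonnegative matrix factorization
#'
#' Factorizes a non-negative expression matrix `X ~ W H` into `r` gene
#' expression programs (columns of `W`, "meta-genes") and per-cell program
#' weights (columns of `H`), while encouraging cells that are close on the
#' deformed-kernel affinity graph to carry similar weights. The objective is
#' \deqn{\|X - WH\|_F^2 + \lambda\, tr(H L H^T)}
#' with `L = D - S` the combinatorial Laplacian of the zero-diagonal
#' affinity graph `S`, minimized by multiplicative updates that preserve
#' non-negativity and never increase the objective. `lam = 0` reduces
#' exactly to standard Lee-Seung NMF.
#'
#' @param X genes x cells non-negative matrix.
#' @param A A `q_affinity` object (or symmetric affinity matrix) over the
#'   same cells, or `NULL` for unregularized NMF.
#' @param r Number of programs; default 16.
#' @param lam Regularization weight >= 0, or `NULL` (default) to
#'   auto-balance: `lam` is set so the two objective terms are equal at
#'   initialization.
#' @param iters Maximum iterations (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param seed Integer seed for the random non-negative initialization;
#'   same seed gives bit-identical fits on a platform.
#' @return Object of class `qnmf`: list with `W` (m x r), `H` (r x n),
#'   `lam`, `r`, `objective_trace` (non-increasing), `iters_run`, `seed`.
#' @examples
#' X <- matrix(rexp(40 * 30), 40, 30)
#' fit <- qnmf(X, r = 3, lam = 0, iters = 100, seed = 1)
#' all(diff(fit$objective_trace) <= 1e-8)
#' @export
qnmf <- function(X, A = NULL, r = 16, lam = NULL, iters = 500,
                 tol = 1e-6, seed = 1) {
  X <- check_expression(X)
  m <- nrow(X); n <- ncol(X)
  if (r > min(m, n)) stop("`r` must not exceed min(genes, cells)")
  if (!is.null(lam) && lam < 0) stop("`lam` must be non-negative")
  if (inherits(A, "q_affinity")) A <- A$A
  if (!is.null(A)) {
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stop("`A` must be an n x n affinity over the same cells as `X`")
    S <- A
    diag(S) <- 0
    deg <- rowSums(S)
  } else {
    S <- NULL
    if (is.null(lam)) lam <- 0
    if (lam > 0) stop("`lam` > 0 requires an affinity graph `A`")
  }

  set.seed(seed)
  scale0 <- sqrt(mean(X) / r)
  W <- matrix(runif(m * r), m, r) * scale0
  H <- matrix(runif(r * n), r, n) * scale0
  eps <- 1e-12

  objective <- function(W, H) {
    err <- sum((X - W %*% H)^2)
    pen <- if (!is.null(S)) {
      HS <- H %*% S
      sum((H * H) %*% deg) - sum(HS * H)   # tr(H L H^T)
    } else 0
    c(err = err, pen = pen)
  }

  ob0 <- objective(W, H)
  if (is.null(lam)) lam <- if (ob0["pen"] > 0) unname(ob0["err"] / ob0["pen"]) else 0
  trace <- numeric(iters + 1L)
  trace[1L] <- ob0["err"] + lam * ob0["pen"]

  it <- 0L
  for (it in seq_len(iters)) {
    # W update (standard Lee-Seung)
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    # H update with Laplacian-penalty split: + lam H S in numerator,
    # + lam H D in denominator
    num <- t(W) %*% X
    den <- (t(W) %*% W) %*% H
    if (!is.null(S) && lam > 0) {
      num <- num + lam * (H %*% S)
      den <- den + lam * sweep(H, 2, deg, `*`)
    }
    H <- H * num / (den + eps)
    ob <- objective(W, H)
    trace[it + 1L] <- ob["err"] + lam * ob["pen"]
    if (abs(trace[it] - trace[it + 1L]) <= tol * max(trace[it], eps)) break
  }

  structure(
    list(W = `dimnames<-`(W, list(rownames(X), paste0("GEP", seq_len(r)))),
         H = `dimnames<-`(H, list(paste0("GEP", seq_len(r)), colnames(X))),
         lam = lam, r = r, objective_trace = trace[seq_len(it + 1L)],
         iters_run = it, seed = seed),
    class = "qnmf"
  )
}

#' @method print qnmf
#' @export
print.qnmf <- function(x, ...) {
  cat(sprintf("qnmf: %d genes x %d cells, r = %d, lam = %.4g\n",
              nrow(x$W), ncol(x$H), x$r, x$lam))
  cat(sprintf("  %d iterations, objective %.6g -> %.6g\n",
              x$iters_run, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Project new expression profiles onto learned programs
#'
#' Column-wise non-negative least squares: each new profile is deconvolved
#' linearly into the learned program basis,
#' `H_new[, j] = argmin_{h >= 0} || Y[, j] - W h ||^2`.
#'
#' @param W m x r non-negative program matrix (or a `qnmf` fit).
#' @param Y m x p matrix of new profiles; gene dimension must match `W`
#'   (align gene identifiers upstream).
#' @return r x p non-negative weight matrix.
#' @export
project_profiles <- function(W, Y) {
  if (inherits(W, "qnmf")) W <- W$W
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(W))
    stop(sprintf("gene dimension mismatch: W has %d genes, Y has %d",
                 nrow(W), nrow(Y)))
  H <- vapply(seq_len(ncol(Y)), function(j) {
    pracma::lsqnonneg(W, Y[, j])$x
  }, numeric(ncol(W)))
  H <- matrix(H, nrow = ncol(W))
  dimnames(H) <- list(colnames(W), colnames(Y))
  H
}

#' Binarize program weights by sparsity
#'
#' Indicator of a non-zero weight: exact zeros produced by multiplicative
#' updates or NNLS map to 0, anything else to 1. Values below
#' `1e-12 * max(h)` are treated as numerical zeros.
#'
#' @param h Non-negative weight vector.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' binarize_weights(c(0, 0.3, 0))  # 0 1 0
#' @export
binarize_weights <- function(h) {
  if (any(h < 0)) stop("`h` must be non-negative")
  if (length(h) == 0L || max(h) == 0) return(rep(0L, length(h)))
  as.integer(h > 1e-12 * max(h))
}

#' Tidy a qnmf fit
#'
#' Long-format tibble of factor loadings, broom style.
#'
#' @param x A `qnmf` object.
#' @param matrix `"W"` for gene loadings (gene, program, loading) or `"H"`
#'   for cell weights (program, cell, weight).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.qnmf <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::tibble(
      gene = rep(rownames(x$W), times = ncol(x$W)),
      program = rep(colnames(x$W), each = nrow(x$W)),
      loading = as.vector(x$W)
    )
  } else {
    tibble::tibble(
      program = rep(rownames(x$H), times = ncol(x$H)),
      cell = rep(colnames(x$H), each = nrow(x$H)),
      weight = as.vector(x$H)
    )
  }
}

#' Glance at a qnmf fit
#'
#' @param x A `qnmf` object.
#' @param ... Unused.
#' @return One-row tibble with `r`, `lam`, `iters`, `objective`, and the
#'   relative reconstruction error.
#' @export
glance.qnmf <- function(x, ...) {
  tibble::tibble(
    r = x$r, lam = x$lam, iters = x$iters_run,
    objective = x$objective_trace[length(x$objective_trace)],
    initial_objective = x$objective_trace[1]
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Save and load a fitted model archive
#'
#' Round-trips a `qnmf` fit through a single JSON archive (factors with
#' their identifiers, penalty weight, objective trace, seed), at near
#' machine precision.
#'
#' @param fit A `qnmf` object.
#' @param path Archive path (`.json`).
#' @return `qnmf_save` returns `path` invisibly; `qnmf_load` returns the
#'   restored `qnmf` object.
#' @export
qnmf_save <- function(fit, path) {
  stopifnot(inherits(fit, "qnmf"))
  payload <- list(
    genes = rownames(fit$W), cells = colnames(fit$H),
    programs = colnames(fit$W),
    W = unname(fit$W), H = unname(fit$H),
    lam = fit$lam, r = fit$r,
    objective_trace = fit$objective_trace,
    iters_run = fit$iters_run, seed = fit$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname qnmf_save
#' @export
qnmf_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(p$W, ncol = p$r, dimnames = list(p$genes, p$programs))
  H <- matrix(p$H, nrow = p$r, dimnames = list(p$programs, p$cells))
  structure(list(W = W, H = H, lam = p$lam, r = p$r,
                 objective_trace = p$objective_trace,
                 iters_run = p$iters_run, seed = p$seed),
            class = "qnmf")
}
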