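#' One-dimensional earth-mover's distance
#'
#' Wasserstein-1 distance between the empirical distributions of two
#' samples: the area between their empirical CDFs. Symmetric, and zero iff
#' the empirical distributions coincide.
#'
#' @param a,b Non-empty numeric samples.
#' @return Non-negative scalar.
#' @examples
#' emd_1d(0, 1)                 # 1
#' emd_1d(c(0, 1), c(0.5, 0.5)) # 0.5
#' @export
emd_1d <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  z <- sort(unique(c(a, b)))
  if (length(z) == 1L) return(0)
  Fa <- ecdf(a)(z)
  Fb <- ecdf(b)(z)
  nz <- length(z)
  sum(abs(Fa[-nz] - Fb[-nz]) * diff(z))
}

#' EMD permutation test
#'
#' Two-sample test with the earth-mover's distance as statistic: group
#' labels are permuted across the pooled sample `n_perm` times and the
#' p-value uses the add-one convention
#' `p = (1 + #\{EMD_perm >= EMD_obs\}) / (1 + n_perm)`, so p is never zero.
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of permutations, >= 99; default 999.
#' @param seed Integer seed.
#' @param feature_id Optional identifier carried into the result.
#' @return One-row tibble: `feature_id`, `statistic` (observed EMD),
#'   `p_value`, `q_value` (`NA`, filled by family-wise correction).
#' @export
emd_perm_test <- function(a, b, n_perm = 999, seed = 1, feature_id = NA_character_) {
  if (n_perm < 99) stop("`n_perm` must be at least 99")
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  obs <- emd_1d(a, b)
  set.seed(seed)
  ord <- order(pool)
  z <- pool[ord]
  gaps <- diff(z)
  lab0 <- c(rep(1L, na), rep(0L, n - na))
  # permuted group indicators, rows ordered by pooled value
  G <- replicate(n_perm, sample(lab0))[ord, , drop = FALSE]
  cumA <- apply(G, 2, cumsum)
  idx <- seq_len(n - 1L)
  Fa <- cumA[idx, , drop = FALSE] / na
  Fb <- (idx - cumA[idx, , drop = FALSE]) / (n - na)
  perm <- colSums(abs(Fa - Fb) * gaps)
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  tibble::tibble(feature_id = feature_id, statistic = obs,
                 p_value = p, q_value = NA_real_)
}

#' Mann-Whitney U test (rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test with tie-corrected normal
#' approximation (exact for small untied samples), via
#' [stats::wilcox.test()]. The statistic reported is U for the first
#' sample (the number of (a, b) pairs with a > b, ties counted half).
#'
#' @inheritParams emd_perm_test
#' @return One-row tibble: `feature_id`, `statistic` (U), `p_value`,
#'   `q_value` (`NA`).
#' @export
u_test <- function(a, b, feature_id = NA_character_) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    # complete ties: no evidence of a shift
    return(tibble::tibble(feature_id = feature_id,
                          statistic = length(a) * length(b) / 2,
                          p_value = 1, q_value = NA_real_))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(feature_id = feature_id, statistic = unname(wt$statistic),
                 p_value = wt$p.value, q_value = NA_real_)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] with
#' `method = "BH"`); thresholding the result at `alpha` controls the false
#' discovery rate at `alpha`.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted q-values, same length, each >= its p-value.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Differentially expressed meta-genes
#'
#' Tests each program's per-cell weights between two conditions (EMD
#' permutation test or rank-sum test), corrects across the programs by
#' Benjamini-Hochberg, and returns the programs significant at FDR
#' `alpha`. Applies equally to genes: pass gene-by-cell matrices.
#'
#' @param H_group1,H_group2 r x n weight matrices (programs in rows) for
#'   the two conditions; must share `r`.
#' @param alpha FDR level; default 0.1.
#' @param test `"emd"` or `"u"`.
#' @param n_perm Permutations for the EMD test.
#' @param seed Integer seed.
#' @return Integer vector of significant program indices, with the full
#'   results tibble (`feature_id`, `statistic`, `p_value`, `q_value`,
#'   `significant`) attached as attribute `"results"`.
#' @export
find_demgs <- function(H_group1, H_group2, alpha = 0.1, test = c("emd", "u"),
                       n_perm = 999, seed = 1) {
  test <- match.arg(test)
  if (is.vector(H_group1)) H_group1 <- matrix(H_group1, nrow = 1)
  if (is.vector(H_group2)) H_group2 <- matrix(H_group2, nrow = 1)
  if (nrow(H_group1) != nrow(H_group2))
    stop("the two groups must have the same number of programs")
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  r <- nrow(H_group1)
  ids <- rownames(H_group1)
  if (is.null(ids)) ids <- paste0("GEP", seq_len(r))
  res <- do.call(rbind, lapply(seq_len(r), function(i) {
    if (test == "emd") {
      emd_perm_test(H_group1[i, ], H_group2[i, ], n_perm = n_perm,
                    seed = seed + i, feature_id = ids[i])
    } else {
      u_test(H_group1[i, ], H_group2[i, ], feature_id = ids[i])
    }
  }))
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value <= alpha
  out <- which(res$significant)
  attr(out, "results") <- res
  out
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param setA,setB Vectors treated as sets.
#' @return Scalar in \[0, 1\].
#' @examples
#' jaccard(c(1, 2), c(2, 3))  # 1/3
#' @export
jaccard <- function(setA, setB) {
  u <- union(setA, setB)
  if (length(u) == 0L) return(0)
  length(intersect(setA, setB)) / length(u)
}
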