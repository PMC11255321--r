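#' Parameter bundle for the deformed kernel geometry
#'
#' Collects the handful of knobs that define the q-diffused geometry: the
#' deformation `q`, the inner bandwidth `phi` that soft-thresholds per-gene
#' differences, the neighbourhood size `k` used for the adaptive outer
#' bandwidth, and the quantile driving the inner-bandwidth heuristic.
#'
#' @param q Deformation parameter, in (1, 2]. `q - 1` is the discount factor
#'   applied to each additional order of gene-gene interaction; the limit
#'   q -> 1 recovers plain Euclidean geometry. Default 1.2.
#' @param phi Inner bandwidth (expression units, > 0). Per-gene differences
#'   are divided by `phi` before entering the norm, so differences above
#'   `phi` cascade into higher-order interaction terms. Use `NA` (default)
#'   to have pipeline functions compute it from the data via
#'   [inner_bandwidth()].
#' @param k Neighbourhood size for the adaptive outer bandwidth: each cell's
#'   kernel scale is its k-th nearest deformed norm. Default 15 (cell-graph
#'   scale); local distributional segmentation uses 16.
#' @param quantile Quantile of per-gene scatters used by the inner-bandwidth
#'   heuristic, in (0, 1). Default 0.5 (the median).
#'
#' @return An object of class `qparams`: a list with elements `q`, `alpha`
#'   (always `q - 1`), `phi`, `k`, `quantile`.
#' @examples
#' qparams()
#' qparams(q = 1.5, k = 16)
#' @export
qparams <- function(q = 1.2, phi = NA_real_, k = 15, quantile = 0.5) {
  check_q(q)
  if (is.null(phi)) phi <- NA_real_
  if (!is.na(phi) && (!is.numeric(phi) || length(phi) != 1L || phi <= 0))
    stop("`phi` must be a single positive number (or NA for data-driven choice)")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stop("`quantile` must lie strictly between 0 and 1")
  structure(
    list(q = q, alpha = q - 1, phi = as.numeric(phi),
         k = as.integer(k), quantile = quantile),
    class = "qparams"
  )
}

#' @method print qparams
#' @export
print.qparams <- function(x, ...) {
  cat(sprintf(
    "qparams: q = %g (alpha = %g), phi = %s, k = %d, quantile = %g\n",
    x$q, x$alpha, if (is.na(x$phi)) "auto" else format(x$phi), x$k, x$quantile))
  invisible(x)
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 1 || q > 2)
    stop("`q` must be a single number with 1 < q <= 2")
  invisible(q)
}

#' Deformed exponential and logarithm
#'
#' The q-exponential `exp_q(x) = [1 + (1 - q) x]_+ ^ (1 / (1 - q))` is a
#' polynomial deformation of the exponential that decays by power law for
#' q > 1; `log_q` is its functional inverse on the positive reals. Both
#' reduce to `exp`/`log` in the limit q -> 1.
#'
#' For q > 1 the bracket `1 + (1 - q) x` turns negative when
#' `x > 1 / (q - 1)`; there `exp_q` returns the one-sided limit `Inf`.
#' Kernel evaluations only ever pass non-positive arguments and never reach
#' that region.
#'
#' @param x Numeric vector (any finite values).
#' @param y Numeric vector of positive values.
#' @param q Deformation parameter in (1, 2].
#' @return Numeric vector of the same length as the input.
#' @examples
#' exp_q(0, 1.2)           # 1
#' exp_q(-1, 2)            # 0.5
#' log_q(exp_q(-3, 1.5), 1.5)  # -3
#' @export
exp_q <- function(x, q) {
  check_q(q)
  base <- 1 + (1 - q) * x
  out <- ifelse(base <= 0, Inf, base^(1 / (1 - q)))
  # x = -Inf maps to 0 (base = +Inf, negative exponent)
  out[is.infinite(x) & x < 0] <- 0
  out
}

#' @rdname exp_q
#' @export
log_q <- function(y, q) {
  check_q(q)
  if (any(!is.na(y) & y <= 0)) stop("`log_q` requires y > 0")
  (y^(1 - q) - 1) / (1 - q)
}

#' Deformed addition
#'
#' The q-sum `a %+q% b = a + b + (1 - q) a b`. Applied recursively it
#' generates every order of interaction among its operands; it satisfies
#' `1 + (1 - q)(a qsum b) = (1 + (1 - q) a)(1 + (1 - q) b)`, the identity
#' that makes the deformed norm computable in linear time.
#'
#' @param a,b Numeric vectors (recycled).
#' @inheritParams exp_q
#' @return `a + b + (1 - q) * a * b`.
#' @examples
#' q_sum(-1, -1, 1.2)  # -2.2
#' @export
q_sum <- function(a, b, q) {
  check_q(q)
  a + b + (1 - q) * a * b
}

#' Squared q-diffused norm
#'
#' The deformed squared norm of a difference vector `v`: the Euclidean
#' squared norm plus `alpha`-discounted products of squared components over
#' every non-empty subset of coordinates,
#' `sum_S alpha^(|S|-1) prod_{i in S} v_i^2` with `alpha = q - 1`.
#' Computed in linear time through the log-domain identity
#' `1 + alpha * qnorm2 = prod_i (1 + alpha v_i^2)`, i.e.
#' `qnorm2 = expm1(sum_i log1p(alpha v_i^2)) / alpha`, which is numerically
#' safe even when the unlogged product overflows.
#'
#' When the true value exceeds the double-precision range the function
#' returns `Inf` with a warning; [q_norm_sq_log()] returns the always-finite
#' log-domain value `log(1 + alpha * qnorm2)`.
#'
#' @param v Numeric vector of per-gene differences (finite).
#' @inheritParams exp_q
#' @return A non-negative scalar, at least the Euclidean squared norm.
#' @examples
#' q_norm_sq(c(1, 1, 1), 1.2)  # 3.64 = 3 + 0.2*3 + 0.04
#' @export
q_norm_sq <- function(v, q) {
  check_q(q)
  if (!is.numeric(v) || length(v) < 1L) stop("`v` must be a non-empty numeric vector")
  if (any(!is.finite(v))) stop("`v` must be finite")
  alpha <- q - 1
  s <- sum(log1p(alpha * v^2))
  out <- expm1(s) / alpha
  if (!is.finite(out)) {
    warning("q_norm_sq exceeds the floating-point range; returning Inf ",
            "(use q_norm_sq_log() for the log-domain value)")
  }
  out
}

#' @rdname q_norm_sq
#' @return `q_norm_sq_log` returns `log(1 + (q - 1) * q_norm_sq(v, q))`,
#'   which is finite for any finite `v`.
#' @export
q_norm_sq_log <- function(v, q) {
  check_q(q)
  if (any(!is.finite(v))) stop("`v` must be finite")
  sum(log1p((q - 1) * v^2))
}

#' The q-diffused kernel
#'
#' Kernel value `exp_q(-qnorm2(v / phi) / rho^2)` for a difference vector
#' `v`, with inner bandwidth `phi` scaling individual gene differences and
#' outer bandwidth `rho` scaling the aggregate norm. Equals 1 iff `v = 0`,
#' decreases in each `|v_i|`, and has a heavier-than-Gaussian (power-law)
#' tail for q > 1.
#'
#' @param v Numeric difference vector.
#' @param params A [qparams()] bundle with a concrete (non-`NA`) `phi`.
#' @param rho Outer bandwidth, > 0.
#' @return A scalar in (0, 1].
#' @examples
#' q_kernel(c(0, 0), qparams(phi = 1), rho = 1)  # 1
#' @export
q_kernel <- function(v, params, rho) {
  stopifnot(inherits(params, "qparams"))
  if (is.na(params$phi)) stop("`params$phi` must be set (see inner_bandwidth())")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("`rho` must be a single positive number")
  exp_q(-q_norm_sq(v / params$phi, params$q) / rho^2, params$q)
}
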