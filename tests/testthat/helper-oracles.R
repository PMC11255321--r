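# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's fast paths: subset enumeration for the deformed norm,
# per-pair loops for affinity matrices, permutation enumeration for optimal
# transport.

# deformed squared norm by explicit sum over all non-empty coordinate
# subsets: sum_S alpha^(|S|-1) prod_{i in S} v_i^2
qnorm_bruteforce <- function(v, q) {
  alpha <- q - 1
  m <- length(v)
  stopifnot(m <= 16)
  total <- 0
  for (mask in seq_len(2^m - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    total <- total + alpha^(length(members) - 1) * prod(v[members]^2)
  }
  total
}

# 1-D Wasserstein-1 via explicit optimal assignment: replicate each sample
# to the least common multiple of the sizes (equal unit masses), then
# minimize the mean absolute difference over all assignments by
# permutation enumeration. Exact for tiny samples.
emd_bruteforce <- function(a, b) {
  l <- pracma::Lcm(length(a), length(b))
  stopifnot(l <= 6)  # permutation enumeration is l! assignments
  aa <- rep(a, each = l / length(a))
  bb <- rep(b, each = l / length(b))
  best <- Inf
  for (p in all_perms(seq_len(l))) {
    best <- min(best, mean(abs(aa - bb[p])))
  }
  best
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# per-pair affinity oracle with scalar kernel calls (no matrix fast path)
affinity_bruteforce <- function(X, phi, q, k) {
  n <- ncol(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- q_norm_sq((X[, i] - X[, j]) / phi, q)
  }
  rho <- sqrt(vapply(seq_len(n), function(i) sort(D[i, -i])[k], numeric(1)))
  At <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    At[i, j] <- exp_q(-D[i, j] / rho[i]^2, q)
  }
  (At + t(At)) / 2
}

# planted two-block affinity matrix: strong within, weak between
planted_block_affinity <- function(sizes, within = 0.9, between = 0.01) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  A <- matrix(between, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(labels == b)
    A[idx, idx] <- within
  }
  diag(A) <- 1
  list(A = A, labels = labels)
}

random_expression <- function(m, n, seed = 1) {
  set.seed(seed)
  matrix(rexp(m * n), m, n,
         dimnames = list(paste0("g", seq_len(m)), paste0("c", seq_len(n))))
}

# reference implementation: plain Lee-Seung multiplicative updates with the
# same initialization scheme, kept independent of the package's fitter
reference_nmf_trace <- function(X, r, iters, seed, eps = 1e-12) {
  set.seed(seed)
  scale0 <- sqrt(mean(X) / r)
  W <- matrix(runif(nrow(X) * r), nrow(X), r) * scale0
  H <- matrix(runif(r * ncol(X)), r, ncol(X)) * scale0
  trace <- numeric(iters + 1)
  trace[1] <- sum((X - W %*% H)^2)
  for (it in seq_len(iters)) {
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    H <- H * (t(W) %*% X) / ((t(W) %*% W) %*% H + eps)
    trace[it + 1] <- sum((X - W %*% H)^2)
  }
  trace
}

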