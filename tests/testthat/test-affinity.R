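test_that("inner bandwidth equals the quantile of per-gene pair scatters", {
  # single pair: scatter = (0 - 2)^2 = 4
  X <- rbind(g1 = c(0, 2))
  colnames(X) <- c("a", "b")
  expect_equal(inner_bandwidth(X, 0.5), 2)
  # scatters {4, 0, 16} -> median 4 -> phi 2
  X3 <- rbind(g1 = c(0, 2), g2 = c(1, 1), g3 = c(0, 4))
  colnames(X3) <- c("a", "b")
  expect_equal(inner_bandwidth(X3, 0.5), 2)
  # identity with the O(mn) variance route on random data
  X <- random_expression(30, 15, seed = 5)
  pair_scatter <- apply(X, 1, function(g) mean(as.vector(dist(g))^2))
  expect_equal(inner_bandwidth(X, 0.5),
               sqrt(unname(quantile(pair_scatter, 0.5))), tolerance = 1e-12)
  # degenerate: all genes constant
  Xc <- matrix(3, 4, 5)
  expect_error(inner_bandwidth(Xc), "zero")
})

test_that("pairwise deformed norms match the per-pair oracle and are symmetric", {
  X <- random_expression(8, 5, seed = 2)
  p <- qparams(phi = 1.7)
  D <- pairwise_qnorms(X, p)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(D[i, j], q_norm_sq((X[, i] - X[, j]) / 1.7, 1.2),
                 tolerance = 1e-12)
  }
  # identical cells give a zero entry
  X[, 2] <- X[, 1]
  D <- pairwise_qnorms(X, p)
  expect_equal(D[1, 2], 0)
})

test_that("adaptive bandwidths take the k-th nearest deformed norm", {
  D <- rbind(c(0, 1, 4, 9),
             c(1, 0, 4, 9),
             c(4, 4, 0, 9),
             c(9, 9, 9, 0))
  expect_equal(adaptive_outer_bandwidths(D, 2)[1], 2)  # 2nd nearest sq 4
  expect_equal(adaptive_outer_bandwidths(D, 1),
               sqrt(c(1, 1, 4, 9)))
  # sort-based oracle on random data + permutation equivariance
  X <- random_expression(20, 12, seed = 9)
  D <- pairwise_qnorms(X, qparams(phi = 1))
  rho <- adaptive_outer_bandwidths(D, 4)
  oracle <- sqrt(vapply(1:12, function(i) sort(D[i, -i])[4], numeric(1)))
  expect_equal(unname(rho), oracle)
  perm <- sample(12)
  rho_p <- adaptive_outer_bandwidths(D[perm, perm], 4)
  expect_equal(unname(rho_p), unname(rho)[perm])
  # duplicates: zero bandwidth repaired with a warning
  Ddup <- rbind(c(0, 0, 2), c(0, 0, 2), c(2, 2, 0))
  expect_warning(r <- adaptive_outer_bandwidths(Ddup, 1), "repaired")
  expect_true(all(r > 0))
  expect_error(suppressWarnings(adaptive_outer_bandwidths(matrix(0, 3, 3), 2)),
               "duplicate")
  expect_error(adaptive_outer_bandwidths(D, 0), "k")
})

test_that("affinity matrix is symmetric with unit diagonal and matches oracles", {
  X <- random_expression(25, 10, seed = 4)
  g <- q_affinity(X, qparams(k = 3))
  expect_equal(g$A, t(g$A))
  expect_true(all(diag(g$A) == 1))
  expect_true(all(g$A > 0 & g$A <= 1))
  # full per-pair scalar-kernel oracle
  A_oracle <- affinity_bruteforce(X, phi = g$phi, q = 1.2, k = 3)
  diag(A_oracle) <- 1
  expect_equal(unname(g$A), A_oracle, tolerance = 1e-9)
  # asymmetric one-sided affinities average arithmetically
  D <- pairwise_qnorms(X, qparams(phi = g$phi))
  rho <- adaptive_outer_bandwidths(D, 3)
  one_sided_12 <- exp_q(-D[1, 2] / rho[1]^2, 1.2)
  one_sided_21 <- exp_q(-D[2, 1] / rho[2]^2, 1.2)
  expect_equal(g$A[1, 2], unname((one_sided_12 + one_sided_21) / 2))
})

test_that("q -> 1 affinity reproduces the adaptive Gaussian graph", {
  X <- random_expression(30, 14, seed = 6)
  g1 <- q_affinity(X, qparams(q = 1 + 1e-9, k = 4))
  gg <- q_affinity(X, qparams(k = 4), kernel = "gaussian")
  expect_equal(g1$A, gg$A, tolerance = 1e-5)
})

test_that("affinities are equivariant in cell order and invariant to gene order", {
  X <- random_expression(18, 9, seed = 8)
  g <- q_affinity(X, qparams(k = 3))
  set.seed(1)
  pc <- sample(9)
  gp <- q_affinity(X[, pc], qparams(k = 3))
  expect_equal(unname(gp$A), unname(g$A[pc, pc]), tolerance = 1e-12)
  pg <- sample(18)
  ggn <- q_affinity(X[pg, ], qparams(k = 3))
  expect_equal(ggn$A, g$A, tolerance = 1e-12)
})

test_that("identical cells get affinity 1 after bandwidth repair", {
  X <- random_expression(12, 6, seed = 3)
  X[, 2] <- X[, 1]
  expect_warning(g <- q_affinity(X, qparams(k = 1)), "repaired")
  expect_equal(g$A[1, 2], 1)
})

test_that("Leiden recovers planted blocks, collapses at tiny resolution, and is seeded", {
  pb <- planted_block_affinity(c(10, 10))
  lab <- leiden_cluster(pb$A, resolution = 1, seed = 5)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(adjusted_rand_index(lab, pb$labels), 1)
  lab0 <- leiden_cluster(pb$A, resolution = 1e-4, seed = 5)
  expect_equal(length(unique(lab0)), 1L)
  expect_identical(leiden_cluster(pb$A, seed = 42), leiden_cluster(pb$A, seed = 42))
  expect_error(leiden_cluster(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("adjusted Rand index matches hand values and an independent implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # one cluster vs two balanced classes: contingency table (2, 2) gives
  # index = expected index, hence 0
  expect_equal(adjusted_rand_index(rep(1, 4), c(1, 1, 2, 2)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("count normalization scales cells to the median total then logs", {
  X <- matrix(c(1, 1, 4, 4, 2, 2), 2, 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  N <- normalize_cells(X)
  expect_equal(unname(colSums(expm1(N))), rep(4, 3))
  expect_error(normalize_cells(cbind(X, d = c(0, 0))), "zero total")
})
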