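test_that("rexelation recovers planted spatial structure deterministically", {
  set.seed(1)
  blob1 <- cbind(rnorm(40, 0), rnorm(40, 0))
  blob2 <- cbind(rnorm(40, 20), rnorm(40, 0))
  coords <- rbind(blob1, blob2)
  rmap <- rexelate(coords, R = 2, seed = 3)
  expect_equal(adjusted_rand_index(rmap$assignment, rep(1:2, each = 40)), 1)
  # grid with four planted quadrants
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 10),
                             y = seq(0, 1, length.out = 10)))
  rmap4 <- rexelate(g, R = 4, seed = 1)
  quadrant <- 1 + (g[, 1] > 0.5) + 2 * (g[, 2] > 0.5)
  expect_equal(adjusted_rand_index(rmap4$assignment, quadrant), 1)
  expect_identical(rexelate(coords, 5, seed = 7)$assignment,
                   rexelate(coords, 5, seed = 7)$assignment)
  expect_error(rexelate(coords, R = 1000), "exceed")
  expect_error(rexelate(coords, R = 1), "at least 2")
})

test_that("squared MMD is symmetric, non-negative, and zero on identical samples", {
  X <- random_expression(12, 10, seed = 2)
  Y <- random_expression(12, 8, seed = 3)
  p <- qparams(k = 16, phi = 1)
  expect_equal(mmd_sq(X, X, params = p), 0)
  expect_equal(mmd_sq(X, Y, params = p), mmd_sq(Y, X, params = p))
  expect_gte(mmd_sq(X, Y, params = p), 0)
  expect_gte(mmd_sq(X, Y, params = p, kernel = "gaussian"), 0)
  expect_error(mmd_sq(X[, 0], Y, params = p), "non-empty")
})

test_that("two-point MMD follows the closed form 2 - 2 k(delta)", {
  p <- qparams(phi = 1, k = 16)
  deltas <- c(0.5, 1, 2, 4)
  vals <- vapply(deltas, function(d) {
    mmd_sq(matrix(0), matrix(d), params = p, rho = 1)
  }, numeric(1))
  expected <- 2 - 2 * exp_q(-deltas^2, 1.2)
  expect_equal(vals, expected, tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))  # monotone in |delta|
})

test_that("rexel distances separate shifted distributions and respect duplicates", {
  set.seed(4)
  m <- 30
  base <- matrix(rexp(m * 60), m, 60)
  shifted <- base + 1.5
  X <- cbind(base[, 1:20], base[, 21:40], shifted[, 41:60])
  colnames(X) <- paste0("c", 1:60)
  coords <- cbind(rep(1:3, each = 20) * 10 + rnorm(60, sd = 0.1), rnorm(60))
  sd_ <- spatial_dataset(X, coords)
  rmap <- structure(list(assignment = rep(1:3, each = 20),
                         centroids = cbind(c(10, 20, 30), 0), R = 3),
                    class = "rexel_map")
  D <- rexel_distances(sd_, rmap, qparams(k = 16))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # same-distribution pair below the between-distribution pairs
  expect_lt(D[1, 2], D[1, 3])
  expect_lt(D[1, 2], D[2, 3])
  expect_equal(attr(D, "metric_tag"), "mmd-q")
  # duplicated rexel has zero distance to its twin
  Xdup <- cbind(base[, 1:20], base[, 1:20])
  colnames(Xdup) <- paste0("c", 1:40)
  sd2 <- spatial_dataset(Xdup, cbind(rnorm(40), rnorm(40)))
  rmap2 <- structure(list(assignment = rep(1:2, each = 20),
                          centroids = cbind(0:1, 0), R = 2),
                     class = "rexel_map")
  D2 <- suppressWarnings(rexel_distances(sd2, rmap2, qparams(k = 16)))
  expect_equal(D2[1, 2], 0)
})

test_that("the mean-PCA baseline produces a valid distance matrix", {
  set.seed(5)
  X <- random_expression(25, 50, seed = 5)
  coords <- cbind(runif(50), runif(50))
  sd_ <- spatial_dataset(X, coords)
  rmap <- rexelate(coords, R = 5, seed = 1)
  D <- rexel_pca_distances(sd_, rmap, n_pcs = 3)
  expect_equal(dim(D), c(5L, 5L))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0) && all(D >= 0))
  expect_equal(attr(D, "metric_tag"), "mean-pca")
})

test_that("segmentation recovers planted blocks under both methods", {
  set.seed(6)
  D <- matrix(3 + abs(rnorm(100, sd = 0.1)), 10, 10)
  D[1:5, 1:5] <- abs(rnorm(25, sd = 0.1))
  D[6:10, 6:10] <- abs(rnorm(25, sd = 0.1))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  truth <- rep(1:2, each = 5)
  lab_c <- segment_rexels(D, "community", seed = 2)
  expect_equal(adjusted_rand_index(lab_c, truth), 1)
  lab_h <- segment_rexels(D, "hierarchical", n_clusters = 2)
  expect_equal(adjusted_rand_index(lab_h, truth), 1)
  # count = R gives singletons
  lab_all <- segment_rexels(D, "hierarchical", n_clusters = 10)
  expect_equal(length(unique(lab_all)), 10L)
  # determinism of the community path
  expect_identical(segment_rexels(D, "community", seed = 9),
                   segment_rexels(D, "community", seed = 9))
  expect_warning(lab0 <- segment_rexels(matrix(0, 4, 4), "community"),
                 "degenerate")
  expect_equal(lab0, rep(1L, 4))
})

test_that("spatial silhouette is high for separated blocks, near zero for random labels", {
  set.seed(7)
  cents <- rbind(cbind(rnorm(15, 0, 1), rnorm(15, 0, 1)),
                 cbind(rnorm(15, 10, 1), rnorm(15, 0, 1)))
  labels <- rep(1:2, each = 15)
  expect_gt(spatial_silhouette(labels, cents), 0.8)
  grid <- as.matrix(expand.grid(seq(0, 1, length.out = 8),
                                seq(0, 1, length.out = 8)))
  s_null <- vapply(1:20, function(s) {
    set.seed(s)
    spatial_silhouette(sample(1:2, 64, replace = TRUE), grid)
  }, numeric(1))
  expect_lt(abs(mean(s_null)), 0.1)
  # duplicated centroids across two labels: no spatial separation
  dup <- rbind(grid, grid)
  expect_lt(spatial_silhouette(rep(1:2, each = 64), dup), 0.05)
  expect_error(spatial_silhouette(rep(1, 10), grid[1:10, ]), "single cluster")
})

test_that("striped tissue is segmented correctly end to end", {
  st <- simulate_striped_tissue(n_cells = 400, m_genes = 120, n_stripes = 2,
                                d_signal = 60, total_effect = 150,
                                noise_sd = 1, seed = 11)
  rmap <- rexelate(st$data$coords, R = 32, seed = 1)
  D <- rexel_distances(st$data, rmap, qparams(k = 16))
  seg <- segment_rexels(D, "community", seed = 1)
  rexel_truth <- vapply(split(st$labels, rmap$assignment),
                        function(z) as.integer(names(which.max(table(z)))),
                        integer(1))
  expect_gt(adjusted_rand_index(seg, rexel_truth), 0.6)
})
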