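# PCA shape models, parallel analysis, reconstruction, distances.

test_that("rank-1 data yields one positive eigenvalue and standardized scores", {
  set.seed(1)
  mu <- rnorm(12)
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  X <- t(vapply(c(-1, 0, 1), function(c) mu + c * v, numeric(12)))
  model <- fit_pca(X)
  expect_equal(length(model$eigenvalues), 1L)
  expect_gt(model$eigenvalues[1], 0)
  s <- model$scores_sd[, 1]
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_equal(sd(s), 1, tolerance = 1e-10)
  expect_equal(abs(cor(s, c(-1, 0, 1))), 1, tolerance = 1e-10)
})

test_that("full-rank reconstruction reproduces every input row", {
  set.seed(2)
  X <- matrix(rnorm(20 * 36, sd = 3), 20, 36)
  model <- fit_pca(X)
  scores <- sweep(model$scores_sd, 2, sqrt(model$eigenvalues), `*`)
  Xhat <- sweep(scores %*% t(model$eigenvectors), 2, model$mean_vector, `+`)
  expect_lt(max(abs(Xhat - X)) / max(abs(X)), 1e-6)
})

test_that("PCA recovers the generator spectrum on noise-free data", {
  # averaged over 3 replicate datasets: the one-dataset Monte-Carlo relative
  # error (~4.5% SD at 1000 pooled samples) is non-trivial against 10%
  lam <- rowMeans(vapply(1:3, function(r) {
    cfg <- synthetic_config(n_subjects = 500, n_points = 15, n_modes_true = 3,
                            eigenvalues_true = c(9, 4, 1), noise_sd = 0,
                            seed = 2 + r)
    tr <- generate_population(cfg)$truth
    sc <- pooled_truth_scores(tr)
    X <- sweep(sc %*% t(tr$modes), 2, as.vector(t(tr$mean_shape)), `+`)
    fit_pca(X)$eigenvalues[1:3]
  }, numeric(3)))
  expect_lt(max(abs(lam / c(9, 4, 1) - 1)), 0.10)
})

test_that("dual-trick spectrum agrees with direct covariance eigen-decomposition", {
  set.seed(4)
  X <- matrix(rnorm(12 * 30), 12, 30) %*% diag(runif(30, 0.5, 3))
  model <- fit_pca(X)
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  m <- length(model$eigenvalues)
  expect_lt(max(abs(model$eigenvalues - ev[seq_len(m)]) / ev[1]), 1e-8)
  expect_lt(abs(sum(model$eigenvalues) - sum(diag(cov(X)))) / sum(diag(cov(X))),
            1e-6)
  G <- crossprod(model$eigenvectors)
  expect_lt(max(abs(G - diag(m))), 1e-8)
})

test_that("parallel analysis is deterministic and handles pure noise", {
  set.seed(5)
  X <- matrix(rnorm(100 * 25), 100, 25)
  r1 <- parallel_analysis(X, n_sim = 60, seed = 9)
  r2 <- parallel_analysis(X, n_sim = 60, seed = 9)
  expect_identical(r1$k_retained, r2$k_retained)
  expect_identical(r1$observed_eigenvalues, r2$observed_eigenvalues)

  # percentile95 criterion retains nothing on noise in >= 90% of replicates;
  # the mean criterion (scree intersection) is liberal at rank 0 but stays small
  k0 <- 0L; kmean <- integer(30)
  for (b in 1:30) {
    Z <- matrix(rnorm(100 * 25), 100, 25)
    if (parallel_analysis(Z, n_sim = 60, criterion = "percentile95",
                          seed = b)$k_retained == 0L) k0 <- k0 + 1L
    kmean[b] <- parallel_analysis(Z, n_sim = 60, seed = b)$k_retained
  }
  expect_gte(k0, 27L)
  expect_lte(stats::median(kmean), 1)
})

test_that("parallel analysis recovers a planted rank and degrades with noise", {
  planted <- function(noise_sd, seed) {
    set.seed(seed)
    n <- 200; p <- 50
    B <- rand_basis(p, 3)
    S <- matrix(rnorm(n * 3), n, 3) %*% diag(sqrt(c(100, 50, 25)))
    S %*% t(B) + matrix(rnorm(n * p, 0, noise_sd), n, p)
  }
  expect_equal(parallel_analysis(planted(1, 6), n_sim = 60, seed = 7)$k_retained, 3L)
  # monotone non-increasing in noise variance over a seeded grid
  ks <- vapply(c(1, 4, 10, 40), function(s)
    parallel_analysis(planted(s, 8), n_sim = 60, seed = 8)$k_retained, 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("reconstruct_at_sd follows the linear model geometry", {
  set.seed(6)
  X <- matrix(rnorm(10 * 30, sd = 2), 10, 30)
  model <- fit_pca(X)
  expect_identical(reconstruct_at_sd(model, 1, 0), model$mean_vector)
  up <- reconstruct_at_sd(model, 2, 3); dn <- reconstruct_at_sd(model, 2, -3)
  expect_equal((up + dn) / 2, model$mean_vector, tolerance = 1e-12)
  expect_equal(sqrt(sum((up - model$mean_vector)^2)),
               3 * sqrt(model$eigenvalues[2]), tolerance = 1e-10)
  expect_error(reconstruct_at_sd(model, length(model$eigenvalues) + 1, 1),
               "mode_index")
})

test_that("point-to-surface distances match closed forms", {
  cube <- cube_mesh()
  on_surface <- rbind(c(0.3, 0.4, 0), c(1, 0.5, 0.5), c(0.2, 0, 0.7))
  expect_lt(max(point_to_surface_distance(on_surface, cube)), 1e-9)

  above <- rbind(c(0.5, 0.5, 1.75), c(0.25, 0.75, -0.5))
  expect_equal(as.vector(point_to_surface_distance(above, cube)), c(0.75, 0.5),
               tolerance = 1e-12)

  sph <- sphere_mesh(n_theta = 30, n_phi = 60)
  d <- point_to_surface_distance(matrix(c(1.5, 0, 0), 1, 3), sph)
  expect_equal(as.vector(d), 0.5, tolerance = 0.01)
  expect_identical(attr(d, "method"), "point_to_triangle")

  dc <- point_to_surface_distance(matrix(c(0, 0, 2), 1, 3), sph$points)
  expect_identical(attr(dc, "method"), "nearest_point")
  expect_equal(as.vector(dc), 1, tolerance = 0.01)
})
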