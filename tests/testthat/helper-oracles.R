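# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's own code paths (element-wise loops, direct
# normal equations, direct SVD of the cross-product).

bf_location <- function(left, right) {
  p <- ncol(left)
  ml <- numeric(p); mr <- numeric(p)
  for (j in seq_len(p)) {
    ml[j] <- sum(left[, j]) / nrow(left)
    mr[j] <- sum(right[, j]) / nrow(right)
  }
  s <- 0
  for (j in seq_len(p)) s <- s + (ml[j] - mr[j])^2
  sqrt(s)
}

bf_scale <- function(left, right) {
  avg_res <- function(g) {
    m <- colSums(g) / nrow(g)
    r <- 0
    for (i in seq_len(nrow(g))) {
      s <- 0
      for (j in seq_len(ncol(g))) s <- s + (g[i, j] - m[j])^2
      r <- r + sqrt(s)
    }
    r / nrow(g)
  }
  abs(avg_res(left) - avg_res(right))
}

# Projection metric straight from the SVD of the cross-product.
bf_projection_metric <- function(A, B, j) {
  s <- svd(t(A) %*% B)$d
  sqrt(j - sum(pmin(s[seq_len(j)], 1)^2))
}

# ANCOVA F for the sex term by explicit normal equations: full model
# [1, age, sex] vs reduced [1, age].
bf_ancova_F <- function(scores, sex, age) {
  X1 <- cbind(1, age, as.numeric(sex == "M"))
  X0 <- cbind(1, age)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% scores)
    sum((scores - X %*% beta)^2)
  }
  r1 <- rss(X1); r0 <- rss(X0)
  df2 <- length(scores) - ncol(X1)
  Fst <- (r0 - r1) / (r1 / df2)
  list(F = Fst, p = stats::pf(Fst, 1, df2, lower.tail = FALSE))
}

# Two-way ANOVA mean squares by explicit sums-of-squares loops.
bf_icc_ms <- function(left, right) {
  x <- cbind(left, right); n <- nrow(x); k <- 2
  g <- sum(x) / (n * k)
  ssr <- 0; for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - g)^2
  ssc <- 0; for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - g)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - g)^2
  sse <- sst - ssr - ssc
  c(MSR = ssr / (n - 1), MSC = ssc / (k - 1), MSE = sse / ((n - 1) * (k - 1)))
}

# KS statistic against a fitted normal, by direct max-deviation scan.
bf_ks_stat <- function(x) {
  n <- length(x); xs <- sort(x)
  mu <- mean(x); s <- sd(x)
  dmax <- 0
  for (i in seq_len(n)) {
    Fi <- pnorm(xs[i], mu, s)
    dmax <- max(dmax, abs(i / n - Fi), abs(Fi - (i - 1) / n))
  }
  dmax
}

# Random p x k matrix with orthonormal columns.
rand_basis <- function(p, k) qr.Q(qr(matrix(rnorm(p * k), p, k)))

# Random 3D rotation, translation and scale applied to a point matrix.
rand_similarity <- function(points) {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  s <- exp(runif(1, -0.3, 0.3))
  tr <- runif(3, -30, 30)
  sweep(s * points %*% t(R), 2, tr, `+`)
}

# Axis-aligned unit cube mesh: 8 vertices, 12 triangles.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  shape_sample(points = v, faces = f, sample_id = "cube")
}

# UV-sphere mesh of given radius.
sphere_mesh <- function(n_theta = 24L, n_phi = 48L, radius = 1) {
  th <- seq(0, pi, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  v <- matrix(0, n_theta * n_phi, 3)
  for (i in seq_len(n_theta)) for (j in seq_len(n_phi))
    v[idx(i, j), ] <- radius * c(sin(th[i]) * cos(ph[j]),
                                 sin(th[i]) * sin(ph[j]), cos(th[i]))
  f <- NULL
  for (i in seq_len(n_theta - 1L)) for (j in seq_len(n_phi)) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
               c(idx(i, j + 1L), idx(i + 1L, j), idx(i + 1L, j + 1L)))
  }
  shape_sample(points = v, faces = f, sample_id = "sphere")
}

# Small null synthetic config used across permutation-test checks.
null_config <- function(n_subjects = 15L, n_points = 30L, seed = 1L,
                        noise_sd = 0.05, ...) {
  synthetic_config(n_subjects = n_subjects, n_points = n_points,
                   n_modes_true = 3L, eigenvalues_true = c(4, 2, 1),
                   icc_per_mode = c(0.8, 0.5, 0.3), noise_sd = noise_sd,
                   seed = seed, ...)
}

# Pooled left+right latent score matrix from a ground truth object.
pooled_truth_scores <- function(truth) rbind(truth$scores_left, truth$scores_right)
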