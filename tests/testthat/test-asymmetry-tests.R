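# D-statistics, principal angles, projection metric, permutation engine.

test_that("location_d matches closed forms and the brute-force oracle", {
  expect_equal(location_d(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(location_d(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
  set.seed(1)
  L <- matrix(rnorm(8), 4, 2); R <- matrix(rnorm(8, 1), 4, 2)
  expect_equal(location_d(L, R), bf_location(L, R), tolerance = 1e-12)
  expect_error(location_d(L, matrix(0, 2, 3)), "dimensionality")
})

test_that("scale_d matches closed forms and the brute-force oracle", {
  L <- matrix(c(-1, 1), 2, 1); R <- matrix(c(-2, 2), 2, 1)
  expect_equal(scale_d(L, L), 0)
  expect_equal(scale_d(L, R), 1)
  set.seed(2)
  A <- matrix(rnorm(40), 10, 4); B <- matrix(rnorm(40, 0, 2), 10, 4)
  expect_equal(scale_d(A, B), bf_scale(A, B), tolerance = 1e-12)
})

test_that("principal angles satisfy their defining cases", {
  set.seed(3)
  B <- rand_basis(10, 3)
  expect_lt(max(principal_angles(B, B)), 1e-7)
  e1 <- matrix(c(1, 0), 2, 1); e2 <- matrix(c(0, 1), 2, 1)
  expect_equal(principal_angles(e1, e2), pi / 2)
  # planted rotation between 1-D bases
  for (alpha in c(0.1, 0.7, 1.2)) {
    a <- matrix(c(1, 0), 2, 1)
    b <- matrix(c(cos(alpha), sin(alpha)), 2, 1)
    expect_equal(principal_angles(a, b), alpha, tolerance = 1e-10)
  }
  expect_error(principal_angles(B * 2, B), "orthonormal")
})

test_that("projection metric identities and oracle agreement hold", {
  expect_equal(projection_metric(c(0, 0, 0)), 0)
  expect_equal(projection_metric(pi / 2, 1), 1)
  expect_equal(projection_metric(c(0, pi / 2), 2), 1)
  expect_equal(projection_metric(c(0.4, 0.9), 2, squared = TRUE),
               2 - cos(0.4)^2 - cos(0.9)^2)
  set.seed(4)
  for (rep in 1:10) {
    A <- rand_basis(20, 4); B <- rand_basis(20, 4)
    th <- principal_angles(A, B)
    D <- projection_metric_set(th)
    expect_true(all(diff(D) >= -1e-12))           # non-decreasing in j
    expect_true(all(D <= sqrt(seq_len(4)) + 1e-12))
    for (j in 1:4)
      expect_equal(D[j], bf_projection_metric(A, B, j), tolerance = 1e-10)
    # symmetry
    expect_equal(D[4], projection_metric(principal_angles(B, A)),
                 tolerance = 1e-10)
  }
})

test_that("perm_pvalue implements the counting formula with an add-one option", {
  expect_identical(perm_pvalue(500, 10000), 0.05)
  expect_identical(perm_pvalue(0, 1000), 0)
  expect_equal(perm_pvalue(0, 999, add_one = TRUE), 1 / 1000)
  expect_equal(perm_pvalue(c(10, 20), 100), c(0.1, 0.2))
})

test_that("permutation_test boundary and validation behaviour", {
  set.seed(5)
  # groups far apart, free relabelling of unequal groups: the observed split
  # is essentially never redrawn, so the observed value beats every permuted
  # one and Eq. 1 as printed gives exactly 0
  L <- matrix(rnorm(60), 20, 3); R <- matrix(rnorm(21, 50), 7, 3)
  r <- permutation_test(L, R, "location", n_perm = 200, scheme = "free", seed = 1)
  expect_true(all(r$d_perm < r$d_observed))
  expect_identical(r$p_perm, 0)
  r1 <- permutation_test(L, R, "location", n_perm = 200, scheme = "free",
                         seed = 1, add_one = TRUE)
  expect_equal(r1$p_perm, 1 / 201)
  # under side_swap, the identity/full-swap relabellings are legal redraws and
  # count as ties per the >= rule
  Lp <- matrix(rnorm(40), 10, 4); Rp <- matrix(rnorm(40, 10), 10, 4)
  rs <- permutation_test(Lp, Rp, "location", n_perm = 200, seed = 1)
  expect_identical(rs$p_perm, perm_pvalue(rs$n_exceed, rs$n_perm))
  expect_error(permutation_test(Lp, Rp[1:5, ], "location", scheme = "side_swap",
                                n_perm = 200),
               "paired")
  expect_warning(permutation_test(Lp, Rp, "location", n_perm = 50, seed = 1),
                 "n_perm")
  expect_error(permutation_test(Lp, Rp, "orientation", n_perm = 200), "requires k")
  # determinism
  a <- permutation_test(Lp, Rp, "scale", n_perm = 300, seed = 42)
  b <- permutation_test(Lp, Rp, "scale", n_perm = 300, seed = 42)
  expect_identical(a$d_perm, b$d_perm)
})

test_that("orientation statistic vanishes up to a shared leading subspace", {
  set.seed(6)
  p <- 30; r <- 2
  shared <- rand_basis(p, r)
  extraL <- rand_basis(p, 1); extraR <- rand_basis(p, 1)
  gen <- function(extra) {
    S <- cbind(matrix(rnorm(40 * r), 40, r) %*% diag(c(20, 10)),
               rnorm(40, 0, 1))
    S %*% t(cbind(shared, extra))
  }
  L <- gen(extraL); R <- gen(extraR)
  thL <- principal_angles(shapesym:::.group_basis(L, 3),
                          shapesym:::.group_basis(R, 3))
  D <- projection_metric_set(thL)
  expect_lt(D[r], 0.15)    # shared leading subspace: near zero
  expect_gt(D[3], 0.5)     # third directions differ
})

test_that("p-values are roughly uniform under the paired null", {
  set.seed(7)
  pvals <- replicate(60, {
    cfg <- null_config(seed = sample.int(1e6, 1))
    tr <- generate_population(cfg)$truth
    mu <- as.vector(t(tr$mean_shape))
    L <- sweep(tr$scores_left %*% t(tr$modes), 2, mu, `+`)
    R <- sweep(tr$scores_right %*% t(tr$modes), 2, mu, `+`)
    permutation_test(L, R, "location", n_perm = 199,
                     seed = sample.int(1e6, 1))$p_perm
  })
  # coarse uniformity smoke check (the acceptance suite runs the strict one)
  expect_gt(mean(pvals < 0.5), 0.30)
  expect_lt(mean(pvals < 0.5), 0.70)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("location-test power is monotone in the directional offset", {
  set.seed(8)
  power_at <- function(offset) {
    rej <- 0L
    for (b in 1:120) {
      cfg <- null_config(n_subjects = 15, n_points = 20,
                         seed = 5000 + b + round(1000 * offset),
                         directional_offset = c(offset, 0, 0))
      tr <- generate_population(cfg)$truth
      mu <- as.vector(t(tr$mean_shape))
      L <- sweep(tr$scores_left %*% t(tr$modes), 2, mu, `+`)
      R <- sweep(tr$scores_right %*% t(tr$modes), 2, mu, `+`)
      p <- permutation_test(L, R, "location", n_perm = 199, seed = b)$p_perm
      if (p < 0.05) rej <- rej + 1L
    }
    rej / 120
  }
  pw <- vapply(c(0, 1, 3), power_at, 0)
  expect_true(all(diff(pw) >= -0.05))  # non-decreasing up to binomial noise
  expect_gt(pw[3], 0.9)
  expect_lt(pw[1], 0.15)
})
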